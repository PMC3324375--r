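# Background frequencies, frequency matrices, log-odds and model fitting.

test_that("background frequencies count residues and normalise", {
  # one protein containing each residue i times (i = 1..20 in alphabet order)
  seqs <- paste(rep(AA_STANDARD, times = seq_len(20)), collapse = "")
  omega <- compute_background_frequencies(as_protein_set(c(p = seqs)))
  expect_equal(unname(omega[AA_STANDARD]), seq_len(20) / 210, tolerance = 1e-12)
  expect_equal(sum(omega), 1, tolerance = 1e-12)
})

test_that("degenerate backgrounds error unless smoothed", {
  aaaa <- as_protein_set(c(p = "AAAA"))
  expect_error(compute_background_frequencies(aaaa), "positive")
  omega <- compute_background_frequencies(aaaa, smooth = TRUE)
  expect_true(all(omega > 0))
  expect_equal(sum(omega), 1, tolerance = 1e-12)
  expect_equal(unname(omega["A"]), 5 / 24, tolerance = 1e-12)

  expect_error(compute_background_frequencies(character(0)), "no proteins")
  expect_message(compute_background_frequencies(c(p = "AXAB"), smooth = TRUE),
                 "ignored")
})

test_that("frequency matrices implement the omega-weighted pseudocount", {
  spec <- window_spec()
  wins <- c("DDDDDDDDDDDDDD", "EEEEEEEEDEEEEE")
  fm0 <- build_frequency_matrix(wins, uniform_omega(), kappa = 0, spec = spec)
  expect_equal(fm0["P9", "D"], 0.5, tolerance = 1e-12)
  expect_equal(fm0["P9", "E"], 0.5, tolerance = 1e-12)
  expect_identical(attr(fm0, "n_peptides"), 2L)

  fm1 <- build_frequency_matrix(wins, uniform_omega(), kappa = 1, spec = spec)
  expect_equal(fm1["P9", "D"], (1 + 0.05) / 3, tolerance = 1e-12)
  expect_equal(fm1["P9", "A"], 0.05 / 3, tolerance = 1e-12)
})

test_that("frequency rows sum to one for any pseudocount weight", {
  set.seed(5)
  wins <- random_windows(40)
  for (kappa in c(0, 0.5, 1)) {
    fm <- build_frequency_matrix(wins, default_background(), kappa,
                                 spec = window_spec())
    expect_true(all(abs(rowSums(fm) - 1) < 1e-9))
    expect_true(all(fm >= 0))
  }
})

test_that("P4 constraints filter windows before counting", {
  spec <- window_spec()
  wd <- "AAAAADAADAAAAA"    # D at P4 (index 6) and P1 (index 9)
  we <- "AAAAAEAADAAAAA"    # E at P4
  fm_d <- build_frequency_matrix(c(wd, we), uniform_omega(), 0, "P4_D",
                                 spec = spec)
  expect_identical(attr(fm_d, "n_peptides"), 1L)
  expect_equal(fm_d["P4", "D"], 1, tolerance = 1e-12)
  fm_nd <- build_frequency_matrix(c(wd, we), uniform_omega(), 0, "P4_notD",
                                  spec = spec)
  expect_equal(fm_nd["P4", "E"], 1, tolerance = 1e-12)
  expect_error(build_frequency_matrix(c(wd), uniform_omega(), 0, "P4_notD",
                                      spec = spec), "no windows")
})

test_that("log-odds entries follow the closed form with the epsilon floor", {
  spec <- window_spec()
  num <- matrix(0.05, nrow = 14, ncol = 20,
                dimnames = list(spec$labels, AA_STANDARD))
  m0 <- log_odds_matrix(num, uniform_omega())
  expect_true(all(m0 == 0))
  expect_identical(attr(m0, "max_score"), 0)

  num["P4", "V"] <- 0.4
  m <- log_odds_matrix(num, uniform_omega())
  expect_equal(m["P4", "V"], 3, tolerance = 1e-12)      # log2(0.4 / 0.05)

  num["P2", "A"] <- -0.2
  m2 <- log_odds_matrix(num, uniform_omega(), epsilon = 1e-4)
  expect_equal(m2["P2", "A"], log2(0.002), tolerance = 1e-9)  # ~ -8.966

  m3 <- log_odds_matrix(num, uniform_omega(), mode = "evidence")
  expect_identical(m3["P2", "A"], 0)
  expect_equal(m3["P4", "V"], 3, tolerance = 1e-12)
  expect_true(all(m3 >= 0))

  expect_error(log_odds_matrix(num, uniform_omega(), epsilon = 0), "epsilon")
})

test_that("log-odds matches a brute-force recomputation on random tables", {
  set.seed(21)
  spec <- window_spec()
  omega <- default_background()
  for (rep in 1:20) {
    num <- matrix(stats::runif(280, -0.2, 0.6), nrow = 14,
                  dimnames = list(spec$labels, AA_STANDARD))
    m <- log_odds_matrix(num, omega, epsilon = 1e-4)
    brute <- m
    for (i in 1:14) for (j in 1:20) {
      brute[i, j] <- log2(max(num[i, j], 1e-4) / omega[[AA_STANDARD[j]]])
    }
    expect_equal(unclass(m), unclass(brute), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(attr(m, "max_score"), sum(apply(brute, 1, max)),
                 tolerance = 1e-12)
  }
})

test_that("fitted A-matrix is forced at P1 and the C-branch falls back", {
  spec <- window_spec()
  omega <- uniform_omega()
  set.seed(31)
  pos <- random_windows(30)
  neg <- random_windows(60)
  # guarantee both P4 sub-patterns in both sets
  substr(pos[1:15], 6, 6) <- "D"; substr(pos[16:30], 6, 6) <- "E"
  substr(neg[1:20], 6, 6) <- "D"; substr(neg[21:60], 6, 6) <- "G"
  model <- fit_model(windows_df(pos), windows_df(neg, label = "negative"),
                     omega, kappa = 0)
  # every training window has D at P1, so with kappa = 0 only D is nonzero
  expect_equal(model$matrices$A["P1", "D"], log2(1 / 0.05), tolerance = 1e-12)
  expect_true(all(model$matrices$A["P1", setdiff(AA_STANDARD, "D")] < -5))

  # all positives with D at P4: C2 unrepresented, falls back to B
  pos_d <- vapply(pos, function(w) {
    substr(w, 6, 6) <- "D"; w
  }, "", USE.NAMES = FALSE)
  expect_warning(
    m2 <- fit_model(windows_df(pos_d), windows_df(neg, label = "negative"),
                    omega),
    "falls back to B")
  expect_true(isTRUE(attr(m2$matrices$C2, "fallback")))
  expect_identical(as.numeric(m2$matrices$C2), as.numeric(m2$matrices$B))
})

test_that("specs without a P4 position fall back for both C-matrices", {
  spec <- window_spec(2, 0)
  pos <- c("AAD", "CCD", "EED", "GGD")
  neg <- c("HHD", "KKD", "LLD", "MMD", "PPD")
  expect_warning(
    model <- fit_model(pos, neg, uniform_omega(), spec = spec),
    "no P4")
  expect_identical(as.numeric(model$matrices$C1), as.numeric(model$matrices$B))
  sc <- score_windows(model, "WWD")
  expect_identical(sc$branch, "C2")
})

test_that("model persistence round-trips scores bit-identically", {
  model <- default_model()
  path <- tempfile(fileext = ".model")
  save_model(model, path)
  reloaded <- load_model(path)
  set.seed(77)
  wins <- random_windows(100)
  expect_identical(score_windows(model, wins), score_windows(reloaded, wins))
  expect_identical(reloaded$cutoff, model$cutoff)
  expect_identical(reloaded$spec$length, model$spec$length)
})

test_that("model files are validated on load", {
  model <- default_model()
  path <- tempfile(fileext = ".model")
  save_model(model, path)

  lines <- readLines(path)
  # drop one row of matrix B
  b_start <- grep("^>matrix\tB", lines)
  truncated <- lines[-(b_start + 3)]
  bad <- tempfile(); writeLines(truncated, bad)
  expect_error(load_model(bad), "matrix B.*13")

  wrong_version <- lines
  wrong_version[1] <- "#version\tcasp3scan-model/99"
  bad2 <- tempfile(); writeLines(wrong_version, bad2)
  expect_error(load_model(bad2), "version")

  expect_error(load_model(tempfile()), "not found")
})

test_that("fitting is deterministic: identical inputs, identical bundles", {
  ds <- default_datasets()
  m1 <- fit_model(ds$positives, ds$negatives)
  m2 <- fit_model(ds$positives, ds$negatives)
  p1 <- tempfile(); p2 <- tempfile()
  save_model(m1, p1); save_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
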