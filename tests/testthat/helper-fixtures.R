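# Shared fixtures, built in code. Expensive objects are memoised so several
# test files can reuse one simulation/fit.

.fx <- new.env(parent = emptyenv())

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

write_tmp_sites <- function(df) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tp1_position",
               sprintf("%s\t%d", df$protein_id, df$p1_position)), path)
  path
}

# Windows data.frame in the package's canonical layout.
windows_df <- function(strings, spec = window_spec(), label = "positive") {
  df <- data.frame(protein_id = sprintf("w%03d", seq_along(strings)),
                   position = rep(spec$upstream + 1L, length(strings)),
                   window = strings, label = label,
                   stringsAsFactors = FALSE)
  attr(df, "spec") <- spec
  df
}

# Uniform background over the 20 residues.
uniform_omega <- function() {
  structure(stats::setNames(rep(0.05, 20), AA_STANDARD),
            class = "background_frequencies")
}

# Random window strings with D forced at P1.
random_windows <- function(n, spec = window_spec()) {
  wins <- vapply(seq_len(n), function(i) {
    res <- sample(AA_STANDARD, spec$length, replace = TRUE)
    res[spec$upstream + 1L] <- "D"
    paste(res, collapse = "")
  }, "")
  wins
}

# A model with random matrix entries (no training), for scoring-oracle
# tests that must not depend on fitting.
random_model <- function(seed, spec = window_spec()) {
  set.seed(seed)
  mk <- function(name) {
    m <- matrix(stats::rnorm(spec$length * 20, sd = 2),
                nrow = spec$length, dimnames = list(spec$labels, AA_STANDARD))
    ms <- 0
    for (v in apply(m, 1, max)) ms <- ms + v
    structure(m, class = c("scoring_matrix", "matrix"), name = name,
              max_score = ms, mode = "penalty")
  }
  structure(list(matrices = list(A = mk("A"), B = mk("B"),
                                 C1 = mk("C1"), C2 = mk("C2")),
                 omega = default_background(), spec = spec, kappa = 1,
                 epsilon = 1e-4, cutoff = 30, n_positives = 0L,
                 n_negatives = 0L, version = "casp3scan-model/1"),
            class = "casp3_model")
}

# Independent brute-force scorer: plain loops, no shared code with
# score_windows.
oracle_score <- function(model, window) {
  res <- strsplit(window, "")[[1]]
  spec <- model$spec
  comp <- function(M) {
    raw <- 0
    for (p in seq_along(res)) raw <- raw + M[p, res[p]]
    ms <- attr(M, "max_score")
    if (ms == 0) 0 else 100 * raw / ms
  }
  a <- comp(model$matrices$A)
  b <- comp(model$matrices$B)
  p4 <- match("P4", spec$labels)
  use_c1 <- !is.na(p4) && res[p4] == "D"
  cc <- comp(model$matrices[[if (use_c1) "C1" else "C2"]])
  list(a = a, b = b, c = cc, branch = if (use_c1) "C1" else "C2",
       S = (a + b + cc) / 3)
}

# Per-position argmax peptide of a matrix; ties resolved toward aspartate
# (relevant at zeroed rows, where D is among the maxima), otherwise toward
# the first residue.
argmax_peptide <- function(M) {
  paste(apply(unclass(M), 1, function(row) {
    top <- names(row)[row == max(row)]
    if ("D" %in% top) "D" else top[1]
  }), collapse = "")
}

# The default strong-motif study conditions, shared across files.
default_sim <- function() {
  if (is.null(.fx$sim)) {
    .fx$sim <- simulate_substrates(simulation_config(seed = 42))
  }
  .fx$sim
}

default_datasets <- function() {
  if (is.null(.fx$ds)) {
    sim <- default_sim()
    .fx$ds <- derive_datasets(sim$proteins, sim$annotations)
  }
  .fx$ds
}

default_model <- function() {
  if (is.null(.fx$model)) {
    ds <- default_datasets()
    .fx$model <- fit_model(ds$positives, ds$negatives)
  }
  .fx$model
}

# A small, fast simulation for unit tests that only need plausible data.
small_sim <- function() {
  if (is.null(.fx$small)) {
    .fx$small <- simulate_substrates(simulation_config(
      n_proteins = 40, length_range = c(60, 120), seed = 99))
  }
  .fx$small
}
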