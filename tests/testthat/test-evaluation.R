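# Confusion metrics, ROC/AUC, optimal cutoff, cross-validation, sweep.

test_that("confusion metrics reproduce hand-computed values", {
  perfect <- confusion_metrics(TP = 50, FP = 0, TN = 50, FN = 0)
  expect_equal(perfect$SEN, 1)
  expect_equal(perfect$SPE, 1)
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)

  m <- confusion_metrics(TP = 45, FP = 10, TN = 40, FN = 5)
  expect_equal(m$SEN, 0.9, tolerance = 1e-12)
  expect_equal(m$SPE, 0.8, tolerance = 1e-12)
  expect_equal(m$ACC, 0.85, tolerance = 1e-12)
  expect_equal(m$PPV, 45 / 55, tolerance = 1e-12)
  expect_equal(m$NPV, 40 / 45, tolerance = 1e-12)
  expect_equal(m$MCC, 1750 / sqrt(55 * 50 * 50 * 45), tolerance = 1e-12)
  expect_equal(m$MCC, 0.7035, tolerance = 1e-4)

  und <- confusion_metrics(TP = 0, FP = 0, TN = 10, FN = 5)
  expect_true(is.na(und$PPV))
  expect_true(is.na(und$MCC))
  expect_false(is.na(und$SPE))

  expect_error(confusion_metrics(TP = -1, FP = 0, TN = 1, FN = 0),
               "non-negative")
})

test_that("confusion metrics agree with a binary-vector oracle", {
  set.seed(101)
  for (i in 1:1000) {
    counts <- stats::rpois(4, lambda = 8) + c(1, 0, 1, 0)
    tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
    m <- confusion_metrics(TP = tp, FP = fp, TN = tn, FN = fn)
    label <- c(rep(1, tp + fn), rep(0, tn + fp))
    pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
    expect_equal(m$SEN, mean(pred[label == 1]), tolerance = 1e-12)
    expect_equal(m$SPE, mean(1 - pred[label == 0]), tolerance = 1e-12)
    expect_equal(m$ACC, mean(pred == label), tolerance = 1e-12)
    # MCC is the Pearson correlation of the two binary vectors
    if (stats::sd(pred) > 0 && stats::sd(label) > 0) {
      expect_equal(m$MCC, stats::cor(pred, label), tolerance = 1e-9)
    } else {
      expect_true(is.na(m$MCC))
    }
  }
})

test_that("ROC handles separation, inversion and total ties", {
  r <- roc_and_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_and_auc(c(0.9, 0.8, 0.1, 0.2),
                           c(FALSE, FALSE, TRUE, TRUE))$auc, 0.0)
  expect_equal(roc_and_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_and_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC equals the Mann-Whitney statistic and is rank-invariant", {
  set.seed(55)
  for (i in 1:50) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    scores <- c(stats::rnorm(n1, 1), stats::rnorm(n0))
    if (i %% 3 == 0) scores <- round(scores)     # force ties
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    auc <- roc_and_auc(scores, labels)$auc
    # oracle: tie-adjusted rank-sum statistic
    rk <- rank(scores)
    u <- sum(rk[labels]) - n1 * (n1 + 1) / 2
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
    # second independent oracle
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      labels, scores, direction = "<", quiet = TRUE)))
    expect_equal(auc, proc_auc, tolerance = 1e-9)
    # invariance under strictly increasing transforms
    expect_equal(roc_and_auc(exp(scores / 4), labels)$auc, auc,
                 tolerance = 1e-12)
    expect_equal(roc_and_auc(2 * scores + 7, labels)$auc, auc,
                 tolerance = 1e-12)
  }
})

test_that("optimal cutoff minimises distance to the perfect corner", {
  r <- roc_and_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(optimal_cutoff(r), 2)   # threshold reaching (0, 1)

  curve <- structure(list(points = data.frame(
    threshold = c(Inf, 5, 4, 3),
    fpr = c(0, 0, 0.1, 1),
    tpr = c(0, 0, 0.9, 1))), class = "roc_curve")
  expect_equal(optimal_cutoff(curve), 4)

  # exact tie (both distances are exactly 0.5) resolved toward the higher
  # threshold
  tie <- structure(list(points = data.frame(
    threshold = c(Inf, 9, 2),
    fpr = c(0, 0, 0.5),
    tpr = c(0, 0.5, 1))), class = "roc_curve")
  expect_equal(optimal_cutoff(tie), 9)
})

test_that("cross-validation partitions positives and avoids leakage", {
  ds <- default_datasets()
  cv <- cross_validate(ds$positives, ds$negatives, k = 5, repeats = 2,
                       seed = 3, keep_folds = TRUE)
  n_pos <- nrow(ds$positives)
  for (r in seq_along(cv$folds)) {
    assignment <- cv$folds[[r]]$assignment
    expect_length(assignment, n_pos)
    expect_setequal(unique(assignment), 1:5)
    tested <- unlist(lapply(cv$folds[[r]]$tests, `[[`, "test_pos_keys"))
    # every positive tested exactly once per repeat
    expect_setequal(tested, paste(ds$positives$protein_id,
                                  ds$positives$position))
    expect_identical(anyDuplicated(tested), 0L)
    for (f in cv$folds[[r]]$tests) {
      expect_length(intersect(f$test_pos_keys, f$train_pos_keys), 0)
      # fold-wise policy: no test window was available while fitting
      expect_length(intersect(f$test_neg_keys, f$train_neg_keys), 0)
      test_prot <- unique(sub(" .*", "", f$test_pos_keys))
      train_neg_prot <- unique(sub(" .*", "", f$train_neg_keys))
      expect_length(intersect(test_prot, train_neg_prot), 0)
    }
  }
})

test_that("cross-validation is deterministic given the seed", {
  ds <- default_datasets()
  cv1 <- cross_validate(ds$positives, ds$negatives, k = 5, repeats = 2,
                        seed = 11)
  cv2 <- cross_validate(ds$positives, ds$negatives, k = 5, repeats = 2,
                        seed = 11)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  expect_identical(cv1$pooled_roc$points, cv2$pooled_roc$points)

  cv3 <- cross_validate(ds$positives, ds$negatives, k = 5, repeats = 2,
                        seed = 12)
  expect_false(identical(cv1$per_repeat$AUC, cv3$per_repeat$AUC))
})

test_that("sensitivity is non-increasing along rising cutoffs", {
  ds <- default_datasets()
  cv <- cross_validate(ds$positives, ds$negatives, k = 5, repeats = 1,
                       seed = 4)
  pts <- cv$pooled_roc$points
  ord <- order(pts$threshold)
  expect_false(is.unsorted(rev(pts$tpr[ord])))
})

test_that("the sweep row for one size equals a direct cross-validation", {
  sim <- small_sim()
  tab <- window_size_sweep(sim$proteins, sim$annotations,
                           sizes = data.frame(upstream = 8, downstream = 5),
                           k = 5, repeats = 2, seed = 9)
  ds <- derive_datasets(sim$proteins, sim$annotations)
  cv <- cross_validate(ds$positives, ds$negatives, k = 5, repeats = 2,
                       seed = 9)
  expect_equal(tab$AUC, mean(cv$per_repeat$AUC), tolerance = 1e-12)
  expect_equal(tab$MCC, mean(cv$per_repeat$MCC), tolerance = 1e-12)
  expect_identical(tab$n_positives, nrow(ds$positives))
})

test_that("global policy samples test negatives from the full pool", {
  ds <- default_datasets()
  cv <- cross_validate(ds$positives, ds$negatives, k = 5, repeats = 1,
                       seed = 2, negative_matrix_policy = "global",
                       keep_folds = TRUE)
  expect_s3_class(cv, "cv_report")
  f <- cv$folds[[1]]$tests[[1]]
  # under the global policy training negatives are the whole set
  expect_length(f$train_neg_keys, nrow(ds$negatives))
})
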