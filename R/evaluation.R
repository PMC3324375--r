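# Validation machinery: confusion metrics, ROC/AUC, optimal cutoff,
# repeated k-fold cross-validation with equal negative sampling, and the
# window-size sweep.

#' Confusion-matrix classification metrics
#'
#' Standard definitions; any metric whose denominator is zero is returned
#' as `NA` (an explicit undefined marker), never silently as 0.
#'
#' @param TP,FP,TN,FN non-negative counts. Alternatively pass a single
#'   named vector/list as `TP`.
#' @return list of class `metrics_report`: SEN, SPE, PPV, NPV, ACC, MCC.
#' @export
confusion_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && (is.list(TP) || length(TP) == 4)) {
    counts <- TP
    TP <- counts[["TP"]]; FP <- counts[["FP"]]
    TN <- counts[["TN"]]; FN <- counts[["FN"]]
  }
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion counts are all zero")
  tp <- as.numeric(TP); fp <- as.numeric(FP)
  tn <- as.numeric(TN); fn <- as.numeric(FN)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  structure(list(
    SEN = safe_div(tp, tp + fn),
    SPE = safe_div(tn, tn + fp),
    PPV = safe_div(tp, tp + fp),
    NPV = safe_div(tn, tn + fn),
    ACC = (tp + tn) / (tp + tn + fp + fn),
    MCC = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  ), class = "metrics_report", counts = counts)
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x)
  cat(paste(sprintf("%s = %s", names(vals),
                    ifelse(is.na(vals), "undefined", sprintf("%.4f", vals))),
            collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and area under it
#'
#' Thresholds are swept over the distinct score values (classification rule
#' `score >= threshold`, so tied scores move together); a leading point at
#' threshold `Inf` anchors (0, 0). The AUC is the trapezoidal area under
#' the (FPR, TPR) polyline.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (or 0/1) true class per score.
#' @return list of class `roc_curve`: `points` (data.frame threshold, fpr,
#'   tpr) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Optimal classification cutoff from a ROC curve
#'
#' The threshold of the curve point closest (Euclidean) to the perfect
#' corner (FPR 0, TPR 1); ties are broken toward the higher (more specific)
#' threshold.
#'
#' @param roc a `roc_curve`.
#' @return the optimal threshold (a score value).
#' @export
optimal_cutoff <- function(roc) {
  pts <- roc$points
  d <- sqrt(pts$fpr^2 + (1 - pts$tpr)^2)
  best <- which(d == min(d))
  max(pts$threshold[best])
}

# Collect duplicate warnings during repeated fitting; re-emit each unique
# message once.
collect_warnings <- function(expr) {
  msgs <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = msgs)
}

#' Repeated k-fold cross-validation of the scoring model
#'
#' Per repeat, positives are shuffled into `k` folds. Per fold, a model is
#' fitted on the other k-1 folds and tested on the held-out positives plus
#' an equal-size random sample of negative windows. The negative matrices
#' follow `negative_matrix_policy`:
#' * `"fold-wise"` (default) — fitting uses only negatives from proteins
#'   that host no test-fold positive, and test negatives are sampled from
#'   the remaining (test-protein) negatives, so no negative window is seen
#'   in both roles;
#' * `"global"` — fitting uses all negatives and test negatives are sampled
#'   from all negatives (a literal reading of equal-number sampling, with
#'   possible train/test leakage).
#'
#' Confusion metrics are computed at the model cutoff, pooled over folds;
#' AUC per repeat comes from the pooled fold scores. All randomness flows
#' from `seed`.
#'
#' @param positives,negatives windows data.frames from [derive_datasets()].
#' @param omega background frequencies.
#' @param k folds (default 10).
#' @param repeats repetitions of the whole k-fold experiment (default 10).
#' @param seed RNG seed (required).
#' @param negative_matrix_policy "fold-wise" or "global".
#' @param kappa,epsilon,cutoff model hyper-parameters (see [fit_model()]).
#' @param spec window geometry; default from `positives`.
#' @param keep_folds also return per-repeat fold assignments and the
#'   training/test membership of every fold (for auditing; default FALSE).
#' @return list of class `cv_report`: `per_repeat` (data.frame with AUC and
#'   the confusion metrics per repeat), `summary` (mean and sd per metric),
#'   `pooled_roc` (ROC over all repeats' scores), `optimal_cutoff`, the
#'   configuration, and (with `keep_folds`) `folds`.
#' @export
cross_validate <- function(positives, negatives, omega = default_background(),
                           k = 10, repeats = 10, seed,
                           negative_matrix_policy = c("fold-wise", "global"),
                           kappa = 1, epsilon = 1e-4, cutoff = 30,
                           spec = NULL, keep_folds = FALSE) {
  negative_matrix_policy <- match.arg(negative_matrix_policy)
  if (missing(seed)) stop("seed is required for reproducible cross-validation")
  if (is.null(spec)) spec <- attr(positives, "spec")
  if (nrow(positives) < k) stop("need at least k = ", k, " positive windows")
  if (nrow(negatives) < nrow(positives)) {
    stop("need at least as many negatives as positives")
  }
  set.seed(seed)
  per_repeat <- vector("list", repeats)
  pooled_scores <- numeric(0)
  pooled_labels <- logical(0)
  fit_warnings <- character(0)
  fold_details <- if (keep_folds) vector("list", repeats) else NULL

  for (r in seq_len(repeats)) {
    fold <- sample(rep(seq_len(k), length.out = nrow(positives)))
    if (keep_folds) {
      fold_details[[r]] <- list(assignment = fold, tests = vector("list", k))
    }
    rep_scores <- numeric(0)
    rep_labels <- logical(0)
    counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (f in seq_len(k)) {
      train_pos <- positives[fold != f, , drop = FALSE]
      test_pos <- positives[fold == f, , drop = FALSE]
      if (negative_matrix_policy == "fold-wise") {
        test_prot <- unique(test_pos$protein_id)
        in_test_prot <- negatives$protein_id %in% test_prot
        train_neg <- negatives[!in_test_prot, , drop = FALSE]
        test_neg_pool <- negatives[in_test_prot, , drop = FALSE]
      } else {
        train_neg <- negatives
        test_neg_pool <- negatives
      }
      if (nrow(train_neg) == 0) {
        stop("fold-wise policy left no negatives for fitting; use policy 'global' or more proteins")
      }
      fitted <- collect_warnings(
        fit_model(train_pos$window, train_neg$window, omega, kappa, epsilon,
                  spec, cutoff))
      fit_warnings <- c(fit_warnings, fitted$warnings)
      model <- fitted$value
      n_test_neg <- min(nrow(test_pos), nrow(test_neg_pool))
      test_neg <- test_neg_pool[sample(nrow(test_neg_pool), n_test_neg), ,
                                drop = FALSE]
      if (keep_folds) {
        fold_details[[r]]$tests[[f]] <- list(
          test_pos_keys = paste(test_pos$protein_id, test_pos$position),
          test_neg_keys = paste(test_neg$protein_id, test_neg$position),
          train_pos_keys = paste(train_pos$protein_id, train_pos$position),
          train_neg_keys = paste(train_neg$protein_id, train_neg$position))
      }
      s_pos <- score_windows(model, test_pos$window)$S
      s_neg <- score_windows(model, test_neg$window)$S
      counts <- counts + c(TP = sum(s_pos >= cutoff),
                           FP = sum(s_neg >= cutoff),
                           TN = sum(s_neg < cutoff),
                           FN = sum(s_pos < cutoff))
      rep_scores <- c(rep_scores, s_pos, s_neg)
      rep_labels <- c(rep_labels, rep(TRUE, length(s_pos)),
                      rep(FALSE, length(s_neg)))
    }
    metrics <- confusion_metrics(counts["TP"], counts["FP"],
                                 counts["TN"], counts["FN"])
    per_repeat[[r]] <- data.frame(
      repeat_id = r, AUC = roc_and_auc(rep_scores, rep_labels)$auc,
      SEN = metrics$SEN, SPE = metrics$SPE, PPV = metrics$PPV,
      NPV = metrics$NPV, ACC = metrics$ACC, MCC = metrics$MCC)
    pooled_scores <- c(pooled_scores, rep_scores)
    pooled_labels <- c(pooled_labels, rep_labels)
  }
  if (length(fit_warnings) > 0) {
    for (msg in unique(fit_warnings)) {
      warning(sum(fit_warnings == msg), " of ", repeats * k, " fold fits: ",
              msg, call. = FALSE)
    }
  }
  per_repeat <- do.call(rbind, per_repeat)
  metric_cols <- setdiff(names(per_repeat), "repeat_id")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_repeat[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_repeat[[m]]), numeric(1)),
    row.names = NULL)
  pooled_roc <- roc_and_auc(pooled_scores, pooled_labels)
  structure(list(per_repeat = per_repeat, summary = summary,
                 pooled_roc = pooled_roc,
                 optimal_cutoff = optimal_cutoff(pooled_roc),
                 config = list(k = k, repeats = repeats, seed = seed,
                               negative_matrix_policy = negative_matrix_policy,
                               kappa = kappa, epsilon = epsilon,
                               cutoff = cutoff),
                 folds = fold_details),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation (policy %s, cutoff %g):\n",
              x$config$repeats, x$config$k, x$config$negative_matrix_policy,
              x$config$cutoff))
  s <- x$summary
  cat(paste(sprintf("  %s = %.4f (sd %.4f)", s$metric, s$mean, s$sd),
            collapse = "\n"), "\n")
  cat(sprintf("  optimal cutoff (pooled ROC): %.4g\n", x$optimal_cutoff))
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' Per-repeat rows followed by summary rows, full precision, deterministic
#' formatting.
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pr <- report$per_repeat
  writeLines(paste(names(pr), collapse = "\t"), con)
  for (i in seq_len(nrow(pr))) {
    writeLines(paste(c(pr$repeat_id[i],
                       sprintf("%.10g", unlist(pr[i, -1]))), collapse = "\t"), con)
  }
  s <- report$summary
  writeLines(sprintf("# mean_%s\t%.10g", s$metric, s$mean), con)
  writeLines(sprintf("# sd_%s\t%.10g", s$metric, s$sd), con)
  writeLines(sprintf("# optimal_cutoff\t%.10g", report$optimal_cutoff), con)
  invisible(path)
}

#' Canonical window sizes for the sweep
#'
#' The (upstream, downstream) pairs from the tripeptide P3-P1 up to
#' P23-P19'.
#'
#' @return data.frame with columns upstream, downstream, label.
#' @export
default_sweep_sizes <- function() {
  up <- c(2, 3, 4, 5, 6, 7, 8, 10, 13, 16, 19, 22)
  down <- c(0, 0, 1, 2, 3, 4, 5, 7, 10, 13, 16, 19)
  data.frame(upstream = up, downstream = down,
             label = sprintf("P%d-P%s", up + 1,
                             ifelse(down == 0, "1", paste0(down, "'"))),
             stringsAsFactors = FALSE)
}

#' Cross-validated performance across window sizes
#'
#' For each window geometry the positive/negative datasets are re-derived
#' (the length criterion changes which sites qualify) and cross-validation
#' is run; the table of mean AUC and MCC per size backs a window-size
#' comparison plot.
#'
#' @param proteins a `protein_set`.
#' @param annotations validated annotation data.frame.
#' @param sizes data.frame with columns upstream, downstream (default
#'   [default_sweep_sizes()]).
#' @param omega background frequencies.
#' @param ... passed to [cross_validate()] (k, repeats, seed, policy, ...).
#' @return data.frame: upstream, downstream, label, n_positives,
#'   n_negatives, AUC, MCC (means over repeats).
#' @export
window_size_sweep <- function(proteins, annotations,
                              sizes = default_sweep_sizes(),
                              omega = default_background(), ...) {
  rows <- lapply(seq_len(nrow(sizes)), function(i) {
    spec <- window_spec(sizes$upstream[i], sizes$downstream[i])
    ds <- derive_datasets(proteins, annotations, spec)
    cv <- cross_validate(ds$positives, ds$negatives, omega, spec = spec, ...)
    data.frame(upstream = sizes$upstream[i], downstream = sizes$downstream[i],
               label = if ("label" %in% names(sizes)) sizes$label[i] else NA,
               n_positives = nrow(ds$positives),
               n_negatives = nrow(ds$negatives),
               AUC = mean(cv$per_repeat$AUC),
               MCC = mean(cv$per_repeat$MCC),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
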