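# Frequency and scoring matrices.
#
# All matrices are position x residue: rows are the P-position labels of the
# window spec (P9..P1, P1'..P5' by default), columns the 20 standard amino
# acids. Scoring matrices carry base-2 log-odds against the background
# frequencies, with the numerator floored at a small epsilon so that
# background subtraction (which can drive numerator cells to zero or below)
# yields a strong finite penalty instead of an undefined logarithm.

#' Compute background amino-acid frequencies from a reference proteome
#'
#' Relative frequencies of the 20 standard residues over all supplied
#' sequences. Non-standard letters are ignored with a tally. With
#' `smooth = TRUE` one pseudo-observation per residue keeps every entry
#' positive even for degenerate inputs.
#'
#' @param proteins a `protein_set` (or character vector of sequences).
#' @param smooth add one pseudo-observation per residue (default FALSE).
#' @return A `background_frequencies` vector summing to 1.
#' @export
compute_background_frequencies <- function(proteins, smooth = FALSE) {
  if (length(proteins) == 0) stop("no proteins supplied")
  chars <- unlist(strsplit(as.character(proteins), ""), use.names = FALSE)
  counts <- table(factor(chars, levels = AA_STANDARD))
  n_nonstd <- length(chars) - sum(counts)
  if (n_nonstd > 0) {
    message(n_nonstd, " non-standard residue(s) ignored in background computation")
  }
  counts <- as.numeric(counts)
  if (smooth) counts <- counts + 1
  if (sum(counts) == 0) stop("no standard residues in input")
  if (any(counts == 0)) {
    stop("some residues never occur; background entries must be positive ",
         "(use smooth = TRUE or a larger reference proteome)")
  }
  as_background(stats::setNames(counts / sum(counts), AA_STANDARD))
}

# Split window strings into an n x L character matrix.
window_char_matrix <- function(windows, spec) {
  if (length(windows) == 0) stop("no windows supplied")
  if (any(nchar(windows) != spec$length)) {
    stop("all windows must have length ", spec$length)
  }
  matrix(unlist(strsplit(windows, ""), use.names = FALSE),
         nrow = length(windows), ncol = spec$length, byrow = TRUE)
}

# Row index (1-based within a window) of a P-position label, or NA.
position_index <- function(spec, label) {
  idx <- match(label, spec$labels)
  if (is.na(idx)) NA_integer_ else idx
}

# Filter window strings by the P4 residue ("all", "P4_D", "P4_notD").
filter_by_p4 <- function(windows, spec, constraint) {
  if (constraint == "all") return(windows)
  p4 <- position_index(spec, "P4")
  if (is.na(p4)) stop("window spec has no P4 position; cannot apply constraint")
  res <- substr(windows, p4, p4)
  if (constraint == "P4_D") windows[res == "D"] else windows[res != "D"]
}

#' Build a position-specific frequency matrix
#'
#' Per-position relative residue frequencies over a set of equal-length
#' peptide windows, with an omega-weighted additive pseudocount:
#' `value[pos, aa] = (count[pos, aa] + kappa * omega[aa]) / (N + kappa)`,
#' so every position row sums to 1 for any `kappa >= 0`.
#'
#' @param windows character vector of window strings (or a windows
#'   data.frame, in which case its `window` column is used).
#' @param omega background frequencies (pseudocount weights).
#' @param kappa non-negative pseudocount weight (default 1).
#' @param constraint `"all"`, `"P4_D"` or `"P4_notD"`: restrict to windows
#'   with / without aspartate at P4 before counting.
#' @param spec the [window_spec()]; taken from the data.frame attribute when
#'   `windows` is one.
#' @return A `frequency_matrix`: positions x residues matrix with attributes
#'   `n_peptides`, `constraint`.
#' @export
build_frequency_matrix <- function(windows, omega, kappa = 1,
                                   constraint = c("all", "P4_D", "P4_notD"),
                                   spec = NULL) {
  constraint <- match.arg(constraint)
  if (is.data.frame(windows)) {
    if (is.null(spec)) spec <- attr(windows, "spec")
    windows <- windows$window
  }
  if (is.null(spec)) stop("spec is required when windows is a character vector")
  stopifnot(kappa >= 0)
  omega <- as_background(omega)
  windows <- filter_by_p4(windows, spec, constraint)
  if (length(windows) == 0) {
    stop("no windows left after applying constraint '", constraint, "'")
  }
  chars <- window_char_matrix(windows, spec)
  n <- nrow(chars)
  counts <- t(apply(chars, 2, function(col) {
    table(factor(col, levels = AA_STANDARD))
  }))
  values <- (counts + kappa * matrix(omega, nrow = spec$length, ncol = 20,
                                     byrow = TRUE)) / (n + kappa)
  dimnames(values) <- list(spec$labels, AA_STANDARD)
  structure(values, class = c("frequency_matrix", "matrix"),
            n_peptides = n, constraint = constraint)
}

#' Base-2 log-odds scoring matrix
#'
#' `entry[pos, aa] = log2(max(numerator[pos, aa], epsilon) / omega[aa])`.
#' The numerator may carry zero or negative cells (a positive-minus-negative
#' frequency difference); the epsilon floor keeps the logarithm defined.
#' Two modes interpret such cells:
#' * `"penalty"` (default) — the floored cell keeps its strongly negative
#'   log-odds, penalising residues depleted relative to the background.
#'   Appropriate for a plain frequency-matrix numerator.
#' * `"evidence"` — entries are clamped at zero,
#'   `max(0, log2(max(numerator, epsilon) / omega))`: only residues
#'   enriched beyond both the background and the numerator's subtracted
#'   term score, everything else is silent. Appropriate for
#'   background-subtracted difference numerators, whose role is to remove
#'   noise signals rather than to punish — and whose cells are undefined
#'   (non-positive) wherever the positive and negative sets agree, notably
#'   the whole P1 row.
#'
#' The matrix's `max_score` is the global maximum any peptide can attain:
#' the sum over positions of the per-position maximum entry.
#'
#' @param numerator positions x residues numeric table (a frequency matrix
#'   or a difference of two).
#' @param omega background frequencies.
#' @param epsilon positive floor applied to the numerator before the log.
#' @param name matrix name ("A", "B", "C1", "C2").
#' @param mode `"penalty"` or `"evidence"` (see above).
#' @return A `scoring_matrix` with attributes `name`, `max_score`, `mode`.
#' @export
log_odds_matrix <- function(numerator, omega, epsilon = 1e-4, name = "A",
                            mode = c("penalty", "evidence")) {
  mode <- match.arg(mode)
  if (epsilon <= 0) stop("epsilon must be > 0")
  omega <- as_background(omega)
  numerator <- as.matrix(numerator)
  if (ncol(numerator) != 20) stop("numerator must have 20 residue columns")
  om <- matrix(omega[colnames(numerator)], nrow = nrow(numerator),
               ncol = 20, byrow = TRUE)
  scores <- log2(pmax(numerator, epsilon) / om)
  if (mode == "evidence") scores <- pmax(scores, 0)
  # accumulate in row order, matching the scorer's summation exactly, so
  # the argmax peptide normalises to precisely 100
  max_score <- 0
  for (m in apply(scores, 1, max)) max_score <- max_score + m
  structure(scores, class = c("scoring_matrix", "matrix"), name = name,
            max_score = max_score, mode = mode)
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("Scoring matrix '%s' (%d positions x 20 residues, max score %.4f)\n",
              attr(x, "name"), nrow(x), attr(x, "max_score")))
  print(round(unclass(x), 3))
  invisible(x)
}

# Build one C-matrix (P4 sub-pattern), falling back to B when a sub-pattern
# is unrepresented.
build_c_matrix <- function(positives, negatives, omega, kappa, epsilon,
                           spec, constraint, name, B) {
  pos_sub <- filter_by_p4(positives, spec, constraint)
  neg_sub <- filter_by_p4(negatives, spec, constraint)
  if (length(pos_sub) == 0 || length(neg_sub) == 0) {
    warning("sub-pattern '", constraint, "' unrepresented in ",
            if (length(pos_sub) == 0) "positives" else "negatives",
            "; matrix ", name, " falls back to B")
    out <- B
    attr(out, "name") <- name
    attr(out, "fallback") <- TRUE
    return(out)
  }
  fm_pos <- build_frequency_matrix(pos_sub, omega, kappa, "all", spec)
  fm_neg <- build_frequency_matrix(neg_sub, omega, kappa, "all", spec)
  log_odds_matrix(unclass(fm_pos) - unclass(fm_neg), omega, epsilon, name,
                  mode = "evidence")
}

#' Fit the four-matrix cleavage-site scoring model
#'
#' Builds, from positive (cleaved) and negative (uncleaved aspartate)
#' windows:
#' * `A` — log-odds of the positive frequency matrix against the background;
#' * `B` — log-odds of the positive-minus-negative frequency difference
#'   (background subtraction suppresses signal shared with non-sites);
#' * `C1` / `C2` — background-subtracted log-odds computed separately for
#'   the sub-patterns with and without aspartate at P4, each from the
#'   correspondingly filtered positives and negatives.
#'
#' The difference matrices are built in "evidence" mode (see
#' [log_odds_matrix()]): only cells enriched in positives beyond both the
#' negatives and the background score, all other cells are exactly 0. This
#' keeps the published 0-100 operating scale meaningful and makes the
#' structurally uninformative rows — positions where both training sets
#' are constrained to aspartate (P1 everywhere; P4 in `C1`), where the
#' subtracted numerator annihilates — contribute nothing to any peptide's
#' score or to the normaliser.
#'
#' When the window has no P4 position, or a sub-pattern is unrepresented,
#' the affected C-matrix falls back to `B` with a warning. Fitting is fully
#' deterministic.
#'
#' @param positives,negatives windows data.frames (or character vectors of
#'   window strings with `spec` supplied).
#' @param omega background frequencies (default packaged table).
#' @param kappa pseudocount weight (default 1).
#' @param epsilon log-floor (default 1e-4).
#' @param spec the [window_spec()] (default taken from `positives`).
#' @param cutoff classification score cutoff stored with the model
#'   (default 30).
#' @return A `casp3_model`.
#' @export
fit_model <- function(positives, negatives, omega = default_background(),
                      kappa = 1, epsilon = 1e-4, spec = NULL, cutoff = 30) {
  if (is.data.frame(positives)) {
    if (is.null(spec)) spec <- attr(positives, "spec")
    positives <- positives$window
  }
  if (is.data.frame(negatives)) negatives <- negatives$window
  if (is.null(spec)) stop("spec is required")
  if (length(positives) == 0) stop("no positive windows")
  if (length(negatives) == 0) stop("no negative windows")
  omega <- as_background(omega)

  fm_pos <- build_frequency_matrix(positives, omega, kappa, "all", spec)
  fm_neg <- build_frequency_matrix(negatives, omega, kappa, "all", spec)
  A <- log_odds_matrix(unclass(fm_pos), omega, epsilon, "A")
  B <- log_odds_matrix(unclass(fm_pos) - unclass(fm_neg), omega, epsilon, "B",
                       mode = "evidence")

  if (is.na(position_index(spec, "P4"))) {
    warning("window spec has no P4 position; C1/C2 fall back to B")
    C1 <- C2 <- B
    attr(C1, "name") <- "C1"; attr(C2, "name") <- "C2"
    attr(C1, "fallback") <- attr(C2, "fallback") <- TRUE
  } else {
    C1 <- build_c_matrix(positives, negatives, omega, kappa, epsilon, spec,
                         "P4_D", "C1", B)
    C2 <- build_c_matrix(positives, negatives, omega, kappa, epsilon, spec,
                         "P4_notD", "C2", B)
  }

  if (attr(A, "max_score") <= 0) {
    stop("degenerate model: matrix A has non-positive maximum score")
  }
  for (m in list(B, C1, C2)) {
    ms <- attr(m, "max_score")
    if (ms < 0) {
      stop("degenerate model: matrix ", attr(m, "name"),
           " has negative maximum score")
    }
    if (ms == 0) {
      warning("matrix ", attr(m, "name"),
              " found no enrichment over the negatives; its component scores 0")
    }
  }
  structure(list(matrices = list(A = A, B = B, C1 = C1, C2 = C2),
                 omega = omega, spec = spec, kappa = kappa,
                 epsilon = epsilon, cutoff = cutoff,
                 n_positives = length(positives),
                 n_negatives = length(negatives),
                 version = MODEL_FORMAT_VERSION),
            class = "casp3_model")
}

#' @export
print.casp3_model <- function(x, ...) {
  cat("Caspase-3 cleavage-site scoring model\n")
  print(x$spec)
  cat(sprintf("  trained on %d positive / %d negative windows\n",
              x$n_positives, x$n_negatives))
  cat(sprintf("  kappa = %g, epsilon = %g, cutoff = %g\n",
              x$kappa, x$epsilon, x$cutoff))
  for (m in x$matrices) {
    cat(sprintf("  matrix %-2s max score %.4f%s\n", attr(m, "name"),
                attr(m, "max_score"),
                if (isTRUE(attr(m, "fallback"))) " (fallback to B)" else ""))
  }
  invisible(x)
}
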