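# Window scoring, protein scanning, proteome screening.
#
# A window's final score S is the mean of three components a, b, c. Each
# component is the per-position sum over one scoring matrix, normalised to a
# 100% scale by that matrix's maximum attainable score. The c component is
# taken from matrix C1 when the window carries aspartate at P4 and from C2
# otherwise. Components have no lower bound; 100 is the structural upper
# bound for each component and for S.

# Raw per-window sums over a scoring matrix. chars: n x L character matrix.
raw_matrix_scores <- function(M, chars) {
  L <- nrow(M)
  out <- numeric(nrow(chars))
  for (p in seq_len(L)) out <- out + M[p, chars[, p]]
  out
}

#' Score peptide windows with a fitted model
#'
#' Vectorised scoring: returns one row per window with the normalised
#' components `a`, `b`, `c`, the sub-pattern `branch` ("C1" when P4 is
#' aspartate, "C2" otherwise) and the final score `S = (a + b + c) / 3`.
#'
#' @param model a `casp3_model`.
#' @param windows character vector of window strings matching the model's
#'   window length; standard residues only; aspartate required at P1.
#' @return data.frame with columns `a`, `b`, `c`, `branch`, `S`.
#' @export
score_windows <- function(model, windows) {
  stopifnot(inherits(model, "casp3_model"))
  spec <- model$spec
  if (length(windows) == 0) {
    return(data.frame(a = numeric(0), b = numeric(0), c = numeric(0),
                      branch = character(0), S = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (any(nchar(windows) != spec$length)) {
    stop("window length does not match the model window (", spec$length, ")")
  }
  if (any(!is_standard_window(windows))) {
    stop("windows must contain only the 20 standard residues")
  }
  p1 <- spec$upstream + 1L
  if (any(substr(windows, p1, p1) != "D")) {
    stop("every window must carry aspartate (D) at P1")
  }
  chars <- window_char_matrix(windows, spec)
  norm <- function(name) {
    M <- model$matrices[[name]]
    ms <- attr(M, "max_score")
    # an all-zero evidence matrix carries no information: component is 0
    if (ms == 0) return(rep(0, nrow(chars)))
    100 * raw_matrix_scores(M, chars) / ms
  }
  a <- norm("A")
  b <- norm("B")
  p4 <- position_index(spec, "P4")
  is_c1 <- if (is.na(p4)) rep(FALSE, length(windows)) else chars[, p4] == "D"
  cc <- ifelse(is_c1, norm("C1"), norm("C2"))
  branch <- ifelse(is_c1, "C1", "C2")
  data.frame(a = a, b = b, c = cc, branch = branch, S = (a + b + cc) / 3,
             stringsAsFactors = FALSE)
}

#' Score a single peptide window
#'
#' @param model a `casp3_model`.
#' @param window one window string.
#' @return list with elements `a`, `b`, `c`, `branch`, `S`.
#' @export
score_window <- function(model, window) {
  stopifnot(length(window) == 1)
  df <- score_windows(model, window)
  list(a = df$a, b = df$b, c = df$c, branch = df$branch, S = df$S)
}

#' Scan a protein for candidate cleavage sites
#'
#' Scores every aspartate-centred window that fits fully inside the
#' sequence and contains only standard residues; results are ordered by
#' position. Skipped sites (terminus overhang, non-standard residues) are
#' tallied in the `skipped` attribute.
#'
#' @param model a `casp3_model`.
#' @param protein one sequence string.
#' @param protein_id accession recorded in the output.
#' @param quiet suppress skip-tally messages.
#' @return data.frame with columns protein_id, position, window, a, b, c,
#'   branch, S, predicted (`S >= model$cutoff`).
#' @export
scan_protein <- function(model, protein, protein_id = "query", quiet = TRUE) {
  wins <- enumerate_aspartate_windows(protein, model$spec,
                                      protein_id = protein_id, quiet = quiet)
  scores <- score_windows(model, wins$window)
  out <- cbind(wins[, c("protein_id", "position", "window")], scores)
  out$predicted <- out$S >= model$cutoff
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- attr(wins, "skipped")
  out
}

#' Screen a proteome for high-scoring cleavage sites
#'
#' Scans every protein and keeps predictions with `S >= threshold`. The
#' default threshold of 45 suits discovery screening; use the model cutoff
#' (default 30) for classification.
#'
#' @param model a `casp3_model`.
#' @param proteins a `protein_set`, or a path to a FASTA file.
#' @param threshold minimum final score retained (default 45).
#' @return list of class `screening_report`: `hits` (prediction rows with
#'   `S >= threshold`), `per_protein` (id, n_candidates, n_hits),
#'   `threshold`, and `totals` (proteins screened, proteins with >= 1 hit,
#'   total hits, candidate windows, skipped sites).
#' @export
screen_proteome <- function(model, proteins, threshold = 45) {
  if (is.character(proteins) && length(proteins) == 1 && file.exists(proteins)) {
    proteins <- read_fasta(proteins)
  }
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be a named protein_set or a FASTA path")
  scans <- lapply(ids, function(id) scan_protein(model, proteins[[id]], id))
  skipped <- Reduce(`+`, lapply(scans, attr, "skipped"))
  all_pred <- do.call(rbind, scans)
  hits <- all_pred[all_pred$S >= threshold, , drop = FALSE]
  rownames(hits) <- NULL
  per_protein <- data.frame(
    protein_id = ids,
    n_candidates = vapply(scans, nrow, integer(1)),
    n_hits = vapply(scans, function(s) sum(s$S >= threshold), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(
    hits = hits,
    per_protein = per_protein,
    threshold = threshold,
    totals = c(proteins = length(ids),
               proteins_with_hits = sum(per_protein$n_hits > 0),
               total_hits = nrow(hits),
               candidate_windows = sum(per_protein$n_candidates),
               skipped_terminus = unname(skipped["terminus"]),
               skipped_nonstandard = unname(skipped["nonstandard"]))),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Proteome screen at threshold %g:\n", x$threshold))
  cat(sprintf("  %d proteins screened, %d with >= 1 hit, %d hits over %d candidate windows\n",
              x$totals["proteins"], x$totals["proteins_with_hits"],
              x$totals["total_hits"], x$totals["candidate_windows"]))
  invisible(x)
}

#' Write a prediction table as TSV
#'
#' Scores are printed with full precision; optional summary lines are
#' appended as `#` comments so identical runs produce byte-identical files.
#'
#' @param predictions prediction data.frame from [scan_protein()] or a
#'   screening report's `hits`.
#' @param path output path.
#' @param summary optional named vector appended as comment lines.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, summary = NULL) {
  df <- predictions
  for (col in c("a", "b", "c", "S")) df[[col]] <- sprintf("%.10g", df[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  if (!is.null(summary)) {
    writeLines(sprintf("# %s\t%s", names(summary), as.character(summary)), con)
  }
  invisible(path)
}
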