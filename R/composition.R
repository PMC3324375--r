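# Amino-acid composition of the tetrapeptide motif and its flanking
# regions: single-residue, R-group (acidic / basic / polar / non-polar) and
# hydropathy frequencies, against the background composition.

# Frequencies of a residue-count vector aggregated into classes.
class_frequencies <- function(freqs, classes) {
  vapply(classes, function(members) sum(freqs[members]), numeric(1))
}

# Residue frequencies of a character vector, over the standard alphabet;
# non-standard letters are dropped.
residue_frequencies <- function(chars) {
  counts <- table(factor(chars, levels = AA_STANDARD))
  n <- sum(counts)
  if (n == 0) return(stats::setNames(rep(NA_real_, 20), AA_STANDARD))
  as.numeric(counts) / n
}

#' Composition of the cleavage motif and its flanking regions
#'
#' Per-position frequencies for the tetrapeptide motif P4..P1 (from the
#' positive windows) and pooled frequencies for the regions of
#' `region_lengths` residues immediately before P4 and after P1' (from the
#' substrate sequences, clipped at the termini). Each table is reported as
#' single-residue, R-group-class and hydropathy-class frequencies, with the
#' background composition and its class sums attached for comparison.
#'
#' @param positive_windows windows data.frame of cleaved sites (label
#'   "positive"), window length >= 4 upstream of P1.
#' @param proteins a `protein_set` providing flanking context.
#' @param annotations validated annotations locating each cleaved aspartate.
#' @param region_lengths flank lengths to pool (default c(5, 10, 20, 30, 50)).
#' @param omega background frequencies used as the reference column.
#' @return list of class `composition_report`: `tetrapeptide` (list of
#'   matrices `residue` 4 x 20, `rgroup` 4 x 4, `hydropathy` 4 x 2 with rows
#'   P4..P1), `regions` (same three tables with one row per region, e.g.
#'   "before_5", "after_50", plus `n_residues` counts), and `reference`.
#' @export
composition_analysis <- function(positive_windows, proteins, annotations,
                                 region_lengths = c(5, 10, 20, 30, 50),
                                 omega = default_background()) {
  if (nrow(positive_windows) == 0) stop("no positive windows supplied")
  spec <- attr(positive_windows, "spec")
  if (is.null(spec) || spec$upstream < 3) {
    stop("windows must extend at least to P4 (upstream >= 3)")
  }
  omega <- as_background(omega)
  chars <- window_char_matrix(positive_windows$window, spec)
  tetra_idx <- match(c("P4", "P3", "P2", "P1"), spec$labels)
  tetra_res <- t(vapply(tetra_idx, function(j) residue_frequencies(chars[, j]),
                        numeric(20)))
  dimnames(tetra_res) <- list(c("P4", "P3", "P2", "P1"), AA_STANDARD)

  annotations <- validate_annotations(annotations, proteins)
  region_chars <- function(side, len) {
    unlist(lapply(seq_len(nrow(annotations)), function(i) {
      seq <- proteins[[annotations$protein_id[i]]]
      p1 <- annotations$p1_position[i]
      if (side == "before") {        # region ends just before P4 (= p1 - 3)
        from <- max(1, p1 - 3 - len); to <- p1 - 4
      } else {                        # region starts just after P1
        from <- p1 + 1; to <- min(nchar(seq), p1 + len)
      }
      if (from > to) return(character(0))
      strsplit(substr(seq, from, to), "")[[1]]
    }), use.names = FALSE)
  }
  region_names <- as.vector(outer(c("before", "after"), region_lengths,
                                  paste, sep = "_"))
  sides <- rep(c("before", "after"), times = length(region_lengths))
  lens <- rep(region_lengths, each = 2)
  region_list <- Map(region_chars, sides, lens)
  names(region_list) <- paste(sides, lens, sep = "_")
  region_res <- t(vapply(region_list, residue_frequencies, numeric(20)))
  colnames(region_res) <- AA_STANDARD

  to_classes <- function(res_mat, classes) {
    out <- t(apply(res_mat, 1, class_frequencies, classes = classes))
    colnames(out) <- names(classes)
    out
  }
  structure(list(
    tetrapeptide = list(
      residue = tetra_res,
      rgroup = to_classes(tetra_res, AA_RGROUPS),
      hydropathy = to_classes(tetra_res, AA_HYDROPATHY),
      n_windows = nrow(positive_windows)),
    regions = list(
      residue = region_res,
      rgroup = to_classes(region_res, AA_RGROUPS),
      hydropathy = to_classes(region_res, AA_HYDROPATHY),
      n_residues = vapply(region_list, function(ch)
        sum(ch %in% AA_STANDARD), integer(1))),
    reference = list(
      residue = stats::setNames(as.numeric(omega), AA_STANDARD),
      rgroup = class_frequencies(stats::setNames(as.numeric(omega), AA_STANDARD),
                                 AA_RGROUPS),
      hydropathy = class_frequencies(stats::setNames(as.numeric(omega), AA_STANDARD),
                                     AA_HYDROPATHY))
  ), class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Composition report\n")
  cat(sprintf("  tetrapeptide motif: %d windows\n", x$tetrapeptide$n_windows))
  cat("  R-group frequencies (P4..P1):\n")
  print(round(x$tetrapeptide$rgroup, 3))
  cat("  flanking regions (pooled residues):\n")
  print(x$regions$n_residues)
  invisible(x)
}

#' Write a composition report as TSV
#'
#' Long format: table (tetrapeptide/regions/reference), row (position or
#' region), class scheme, class, frequency.
#'
#' @param report a `composition_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_composition_report <- function(report, path) {
  rows <- list()
  emit <- function(table, mat, scheme) {
    for (i in seq_len(nrow(mat))) {
      rows[[length(rows) + 1]] <<- data.frame(
        table = table, row = rownames(mat)[i], scheme = scheme,
        class = colnames(mat), frequency = as.numeric(mat[i, ]),
        stringsAsFactors = FALSE)
    }
  }
  for (scheme in c("residue", "rgroup", "hydropathy")) {
    emit("tetrapeptide", report$tetrapeptide[[scheme]], scheme)
    emit("regions", report$regions[[scheme]], scheme)
    ref <- report$reference[[scheme]]
    emit("reference", matrix(ref, nrow = 1,
                             dimnames = list("background", names(ref))), scheme)
  }
  out <- do.call(rbind, rows)
  out$frequency <- sprintf("%.10g", out$frequency)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
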