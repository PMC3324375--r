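# Sequence input, window extraction and training-set derivation.
#
# Proteins are held as a named character vector (`protein_set`): names are
# unique accessions, values upper-case amino-acid strings. FASTA parsing is
# delegated to Biostrings. Peptide windows are rows of a data.frame with
# columns protein_id, position (1-based P1 position), window (residue
# string) and label.

#' Construct a protein set from id/sequence pairs
#'
#' @param sequences named character vector (names = accessions) or an
#'   `AAStringSet`.
#' @return A `protein_set`: named upper-case character vector. Sequences
#'   containing letters outside the 20 standard amino acids are kept but a
#'   warning tallies them.
#' @export
as_protein_set <- function(sequences) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences)) stop("sequences must be a character vector or AAStringSet")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs a non-empty identifier")
  if (anyDuplicated(ids)) {
    stop("duplicate protein identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(gsub("[[:space:]]", "", sequences))
  if (any(!nzchar(seqs))) stop("empty sequence for: ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  nonstd <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% AA_STANDARD)
  }, logical(1))
  if (any(nonstd)) {
    warning(sum(nonstd), " sequence(s) contain non-standard residues (kept, flagged): ",
            paste(utils::head(ids[nonstd], 5), collapse = ", "),
            if (sum(nonstd) > 5) ", ..." else "")
  }
  structure(stats::setNames(seqs, ids), class = "protein_set",
            nonstandard = ids[nonstd])
}

#' Read a protein FASTA file
#'
#' One record per header, sequences upper-cased with whitespace stripped,
#' input order preserved. Duplicate identifiers are an error; records with
#' residues outside the 20 standard letters are retained with a warning.
#' The identifier is the first whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @return A `protein_set`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA file: ", path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  as_protein_set(aa)
}

#' Write a protein set to FASTA
#'
#' @param proteins a `protein_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(unclass(proteins))
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Window geometry around the P1 aspartate
#'
#' The default (8, 5) spans P9..P5' (14 residues): 8 residues before and 5
#' after the cleaved aspartate.
#'
#' @param upstream residues before P1 (>= 0).
#' @param downstream residues after P1 (>= 0).
#' @return A `window_spec` with the window length and P-position labels.
#' @export
window_spec <- function(upstream = 8, downstream = 5) {
  stopifnot(upstream >= 0, downstream >= 0)
  labels <- c(paste0("P", (upstream + 1):1),
              if (downstream > 0) paste0("P", 1:downstream, "'"))
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 length = as.integer(upstream + 1L + downstream),
                 labels = labels),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("Window P%d-P%d' (%d residues; %d upstream, %d downstream of P1)\n",
              x$upstream + 1L, x$downstream, x$length, x$upstream, x$downstream))
  invisible(x)
}

#' Read and validate a cleavage-annotation table
#'
#' Tab-separated, header line required (`protein_id<TAB>p1_position`),
#' `#` comment lines allowed. Every row is validated against its protein:
#' the identifier must be known, the position in range, and the residue at
#' that position must be aspartate (D). Exact duplicates are collapsed with
#' a warning.
#'
#' @param path annotation TSV path.
#' @param proteins a `protein_set` used for validation.
#' @return data.frame with columns `protein_id`, `p1_position`.
#' @export
read_cleavage_annotations <- function(path, proteins) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("protein_id", "p1_position") %in% names(tab))) {
    stop("annotation file must have header columns protein_id and p1_position")
  }
  tab <- tab[, c("protein_id", "p1_position")]
  tab$p1_position <- as.integer(tab$p1_position)
  validate_annotations(tab, proteins)
}

#' Validate cleavage annotations against their proteins
#'
#' @param annotations data.frame with `protein_id`, `p1_position`.
#' @param proteins a `protein_set`.
#' @return the validated, de-duplicated data.frame.
#' @export
validate_annotations <- function(annotations, proteins) {
  stopifnot(is.data.frame(annotations),
            all(c("protein_id", "p1_position") %in% names(annotations)))
  unknown <- setdiff(annotations$protein_id, names(proteins))
  if (length(unknown) > 0) {
    stop("annotation references unknown protein(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  for (i in seq_len(nrow(annotations))) {
    id <- annotations$protein_id[i]
    pos <- annotations$p1_position[i]
    seq <- proteins[[id]]
    if (is.na(pos) || pos < 1 || pos > nchar(seq)) {
      stop(sprintf("annotation out of range: protein %s position %s (length %d)",
                   id, pos, nchar(seq)))
    }
    res <- substr(seq, pos, pos)
    if (res != "D") {
      stop(sprintf("annotated residue is not aspartate: protein %s position %d is '%s'",
                   id, pos, res))
    }
  }
  dup <- duplicated(annotations[, c("protein_id", "p1_position")])
  if (any(dup)) {
    warning(sum(dup), " duplicate annotation(s) collapsed")
    annotations <- annotations[!dup, , drop = FALSE]
  }
  rownames(annotations) <- NULL
  annotations
}

#' Extract the peptide window around a P1 aspartate
#'
#' Returns the residues from `p1_position - upstream` to
#' `p1_position + downstream` (1-based, inclusive) when the window lies
#' fully inside the sequence; sites too close to a terminus return `NA`
#' (no padding — such sites do not fulfil the length criterion).
#'
#' @param protein a single sequence string (or a `protein_set` element).
#' @param p1_position 1-based position of the cleaved aspartate.
#' @param spec a [window_spec()].
#' @return the window string, or `NA_character_` when it would overhang a
#'   terminus.
#' @export
extract_window <- function(protein, p1_position, spec = window_spec()) {
  seq <- as.character(protein)[1]
  if (p1_position < 1 || p1_position > nchar(seq)) {
    stop("p1_position out of range")
  }
  if (substr(seq, p1_position, p1_position) != "D") {
    stop(sprintf("residue at position %d is '%s', not D", p1_position,
                 substr(seq, p1_position, p1_position)))
  }
  start <- p1_position - spec$upstream
  end <- p1_position + spec$downstream
  if (start < 1 || end > nchar(seq)) return(NA_character_)
  substr(seq, start, end)
}

# TRUE when a window string contains only the 20 standard residues.
is_standard_window <- function(windows) {
  !grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), windows)
}

# All positions of D residues in a sequence string.
aspartate_positions <- function(seq) {
  which(strsplit(seq, "")[[1]] == "D")
}

# Assemble the canonical windows data.frame.
make_windows <- function(protein_id, position, window, label, spec) {
  df <- data.frame(protein_id = as.character(protein_id),
                   position = as.integer(position),
                   window = as.character(window),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  attr(df, "spec") <- spec
  df
}

#' Enumerate all candidate aspartate windows in a protein
#'
#' One unlabeled window per D residue whose full window fits inside the
#' sequence. Windows containing residues outside the 20 standard letters
#' are skipped; their count is recorded in the `skipped` attribute and in
#' a message.
#'
#' @param protein a single sequence string.
#' @param spec a [window_spec()].
#' @param protein_id accession recorded in the output (default "query").
#' @param quiet suppress the skip-tally message.
#' @return data.frame of windows (columns protein_id, position, window,
#'   label = "unlabeled") with attributes `spec` and `skipped` (named
#'   counts: terminus, nonstandard).
#' @export
enumerate_aspartate_windows <- function(protein, spec = window_spec(),
                                        protein_id = "query", quiet = FALSE) {
  seq <- as.character(protein)[1]
  dpos <- aspartate_positions(seq)
  fits <- dpos[dpos - spec$upstream >= 1 & dpos + spec$downstream <= nchar(seq)]
  n_terminus <- length(dpos) - length(fits)
  if (length(fits) == 0) {
    out <- make_windows(character(0), integer(0), character(0), character(0), spec)
    attr(out, "skipped") <- c(terminus = n_terminus, nonstandard = 0L)
    return(out)
  }
  wins <- substring(seq, fits - spec$upstream, fits + spec$downstream)
  std <- is_standard_window(wins)
  n_nonstd <- sum(!std)
  if (!quiet && (n_terminus + n_nonstd) > 0) {
    message(sprintf("%s: skipped %d site(s) too close to a terminus, %d with non-standard residues",
                    protein_id, n_terminus, n_nonstd))
  }
  out <- make_windows(protein_id, fits[std], wins[std], "unlabeled", spec)
  attr(out, "skipped") <- c(terminus = n_terminus, nonstandard = as.integer(n_nonstd))
  out
}

#' Derive positive and negative training windows
#'
#' Positives are the windows at annotated P1 positions; negatives are all
#' other aspartate-centred windows in the same substrate proteins, on the
#' assumption that unmapped aspartates in a known substrate are uncleaved.
#' Both sets are restricted to windows that fit fully inside the sequence
#' and contain only standard residues; they are disjoint by
#' (protein, position).
#'
#' @param proteins a `protein_set`.
#' @param annotations validated annotation data.frame.
#' @param spec a [window_spec()].
#' @param quiet suppress skip-tally messages.
#' @return list with elements `positives` and `negatives` (windows
#'   data.frames labelled accordingly) and `skipped` (total skip tallies).
#' @export
derive_datasets <- function(proteins, annotations, spec = window_spec(),
                            quiet = TRUE) {
  annotations <- validate_annotations(annotations, proteins)
  ids <- unique(annotations$protein_id)
  per_protein <- lapply(ids, function(id) {
    enumerate_aspartate_windows(proteins[[id]], spec, protein_id = id,
                                quiet = quiet)
  })
  all_windows <- do.call(rbind, per_protein)
  skipped <- Reduce(`+`, lapply(per_protein, attr, "skipped"))
  key <- paste(all_windows$protein_id, all_windows$position)
  pos_key <- paste(annotations$protein_id, annotations$p1_position)
  is_pos <- key %in% pos_key
  positives <- all_windows[is_pos, , drop = FALSE]
  negatives <- all_windows[!is_pos, , drop = FALSE]
  positives$label <- rep("positive", nrow(positives))
  negatives$label <- rep("negative", nrow(negatives))
  if (nrow(positives) == 0) stop("no annotated site yields a full-length window")
  rownames(positives) <- rownames(negatives) <- NULL
  attr(positives, "spec") <- attr(negatives, "spec") <- spec
  list(positives = positives, negatives = negatives, skipped = skipped)
}
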