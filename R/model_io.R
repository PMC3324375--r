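# Model persistence: a versioned plain-text bundle with a key-value header,
# the background-frequency vector, and one TSV block per scoring matrix.
# Numbers are written with 17 significant digits so a save/load round trip
# reproduces scores bit-identically.

MODEL_FORMAT_VERSION <- "casp3scan-model/1"

fmt_num <- function(x) sprintf("%.17g", x)

#' Save a scoring model as a plain-text bundle
#'
#' @param model a `casp3_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "casp3_model"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#version\t", model$version)
  w("kappa\t", fmt_num(model$kappa))
  w("epsilon\t", fmt_num(model$epsilon))
  w("cutoff\t", fmt_num(model$cutoff))
  w("upstream\t", model$spec$upstream)
  w("downstream\t", model$spec$downstream)
  w("n_positives\t", model$n_positives)
  w("n_negatives\t", model$n_negatives)
  w(">omega")
  w(paste(AA_STANDARD, collapse = "\t"))
  w(paste(fmt_num(model$omega[AA_STANDARD]), collapse = "\t"))
  for (m in model$matrices) {
    w(">matrix\t", attr(m, "name"), "\tmax_score\t", fmt_num(attr(m, "max_score")),
      if (isTRUE(attr(m, "fallback"))) "\tfallback" else "")
    w(paste(c("position", colnames(m)), collapse = "\t"))
    for (i in seq_len(nrow(m))) {
      w(paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t"))
    }
  }
  invisible(path)
}

#' Load a scoring model from a plain-text bundle
#'
#' Validates the format version and the shape of every matrix block against
#' the window geometry declared in the header.
#'
#' @param path bundle path written by [save_model()].
#' @return A `casp3_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#version\t")) {
    stop("malformed model file: missing version line")
  }
  version <- sub("^#version\t", "", lines[1])
  if (version != MODEL_FORMAT_VERSION) {
    stop("unsupported model format version '", version, "' (expected '",
         MODEL_FORMAT_VERSION, "')")
  }
  header_end <- match(">omega", lines)
  if (is.na(header_end)) stop("malformed model file: missing omega block")
  kv <- strsplit(lines[2:(header_end - 1)], "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  get_kv <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("malformed model file: missing header key '", key, "'")
    as.numeric(vals[i])
  }
  spec <- window_spec(get_kv("upstream"), get_kv("downstream"))

  omega_names <- strsplit(lines[header_end + 1], "\t", fixed = TRUE)[[1]]
  omega_vals <- as.numeric(strsplit(lines[header_end + 2], "\t", fixed = TRUE)[[1]])
  omega <- as_background(stats::setNames(omega_vals, omega_names))

  starts <- grep("^>matrix\t", lines)
  if (length(starts) != 4) stop("malformed model file: expected 4 matrix blocks, found ",
                                length(starts))
  ends <- c(starts[-1] - 1L, length(lines))
  matrices <- list()
  for (b in seq_along(starts)) {
    head_fields <- strsplit(lines[starts[b]], "\t", fixed = TRUE)[[1]]
    name <- head_fields[2]
    max_score <- as.numeric(head_fields[4])
    fallback <- length(head_fields) >= 5 && head_fields[5] == "fallback"
    block <- lines[(starts[b] + 1):ends[b]]
    block <- block[nzchar(block)]
    cols <- strsplit(block[1], "\t", fixed = TRUE)[[1]][-1]
    rows <- block[-1]
    if (length(rows) != spec$length || length(cols) != 20) {
      stop(sprintf("matrix %s has shape %d x %d, expected %d x 20",
                   name, length(rows), length(cols), spec$length))
    }
    cells <- strsplit(rows, "\t", fixed = TRUE)
    values <- t(vapply(cells, function(r) as.numeric(r[-1]), numeric(20)))
    dimnames(values) <- list(vapply(cells, `[`, "", 1), cols)
    m <- structure(values, class = c("scoring_matrix", "matrix"),
                   name = name, max_score = max_score)
    if (fallback) attr(m, "fallback") <- TRUE
    matrices[[name]] <- m
  }
  missing <- setdiff(c("A", "B", "C1", "C2"), names(matrices))
  if (length(missing) > 0) stop("model file missing matrix block(s): ",
                                paste(missing, collapse = ", "))
  structure(list(matrices = matrices[c("A", "B", "C1", "C2")],
                 omega = omega, spec = spec,
                 kappa = get_kv("kappa"), epsilon = get_kv("epsilon"),
                 cutoff = get_kv("cutoff"),
                 n_positives = as.integer(get_kv("n_positives")),
                 n_negatives = as.integer(get_kv("n_negatives")),
                 version = version),
            class = "casp3_model")
}

#' Export one scoring matrix as a TSV table
#'
#' Plain positions x residues table (for heat-map style inspection in other
#' tools).
#'
#' @param model a `casp3_model`.
#' @param name which matrix ("A", "B", "C1", "C2").
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_matrix_tsv <- function(model, name, path) {
  m <- model$matrices[[name]]
  if (is.null(m)) stop("no matrix named '", name, "'")
  df <- data.frame(position = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
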