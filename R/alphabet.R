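# Amino-acid alphabet, side-chain classes and the packaged background
# composition used as the default log-odds denominator.

#' The 20 standard amino acids
#'
#' One-letter codes in the conventional alphabetical-by-code order used for
#' matrix columns throughout the package.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Side-chain (R-group) classes
#'
#' Partition of the 20 standard residues into acidic, basic, polar and
#' non-polar classes, as used for flanking-composition analysis.
#'
#' @format Named list of character vectors partitioning [AA_STANDARD].
#' @export
AA_RGROUPS <- list(
  acidic    = c("D", "E"),
  basic     = c("H", "K", "R"),
  polar     = c("N", "Q", "S", "T", "Y"),
  nonpolar  = c("A", "L", "P", "M", "G", "V", "I", "F", "W", "C")
)

#' Hydropathy classes
#'
#' Hydrophobic residues are those with positive Kyte-Doolittle hydropathy;
#' the remainder are treated as hydrophilic. This split is a documented
#' convention of this package, not a universal standard.
#'
#' @format Named list with elements `hydrophobic` and `hydrophilic`.
#' @export
AA_HYDROPATHY <- list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
  hydrophilic = c("R", "N", "D", "E", "Q", "G", "H", "K", "P", "S", "T", "Y")
)

# Background amino-acid composition of reviewed human proteins (UniProtKB
# proteome-scale composition statistics, relative frequencies). Used as the
# packaged default when no reference proteome is supplied; a user-supplied
# proteome always overrides it.
.default_omega_raw <- c(
  A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
  I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
  R = 5.6, S = 8.3, T = 5.3, V = 6.0, W = 1.2, Y = 2.7
)

#' Packaged default background frequencies
#'
#' Natural amino-acid frequencies of a human-proteome-like composition
#' (relative frequencies over the 20 standard residues, summing to 1).
#' Serves as the default background \eqn{\Omega} for log-odds scoring when
#' the user does not supply a reference proteome.
#'
#' @return A `background_frequencies` object: a named numeric vector over
#'   [AA_STANDARD] summing to 1.
#' @seealso [compute_background_frequencies()] to derive \eqn{\Omega} from a
#'   reference proteome.
#' @export
default_background <- function() {
  omega <- .default_omega_raw[AA_STANDARD] / sum(.default_omega_raw)
  structure(omega, class = "background_frequencies")
}

#' Validate a background-frequency vector
#'
#' @param omega named numeric vector over the 20 standard residues.
#' @return `omega`, reordered to [AA_STANDARD], classed.
#' @keywords internal
as_background <- function(omega) {
  if (!is.numeric(omega) || is.null(names(omega)) ||
      !setequal(names(omega), AA_STANDARD)) {
    stop("background frequencies must be a named numeric vector over the 20 standard residues")
  }
  omega <- omega[AA_STANDARD]
  if (any(omega <= 0)) stop("background frequencies must all be > 0")
  if (abs(sum(omega) - 1) > 1e-9) stop("background frequencies must sum to 1")
  structure(omega, class = "background_frequencies")
}

#' @export
print.background_frequencies <- function(x, ...) {
  cat("Background amino-acid frequencies (sum = 1):\n")
  print(round(unclass(x), 4))
  invisible(x)
}
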