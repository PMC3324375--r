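# Synthetic substrate simulator: background proteins with cleavage windows
# sampled from a known generating PSSM, so model fitting, cross-validation
# and screening are testable end-to-end and parameter recovery is
# measurable against the generator.

# Build one PSSM row: `mass` on the listed residues (proportional to their
# weights), the remainder spread as the background.
pssm_row <- function(omega, prefs, mass) {
  row <- as.numeric(omega) * (1 - mass)
  names(row) <- AA_STANDARD
  row[names(prefs)] <- row[names(prefs)] + mass * prefs / sum(prefs)
  row / sum(row)
}

#' Construct a generating PSSM from per-position residue preferences
#'
#' Positions not named in `preferences` are pure background; named positions
#' put `mass` of their probability on the listed residues (proportional to
#' the given weights) and the rest on the background. The P1 row is always
#' forced to aspartate.
#'
#' @param preferences named list: P-position label -> named numeric weights,
#'   e.g. `list(P4 = c(D = 1), "P1'" = c(G = 2, S = 1))`.
#' @param mass probability mass assigned to the preferred residues
#'   (default 0.85).
#' @param spec window geometry (default P9-P5').
#' @param omega background frequencies.
#' @return positions x residues probability matrix (rows sum to 1).
#' @export
make_generating_pssm <- function(preferences = list(), mass = 0.85,
                                 spec = window_spec(),
                                 omega = default_background()) {
  omega <- as_background(omega)
  pssm <- matrix(as.numeric(omega), nrow = spec$length, ncol = 20,
                 byrow = TRUE, dimnames = list(spec$labels, AA_STANDARD))
  for (label in names(preferences)) {
    i <- position_index(spec, label)
    if (is.na(i)) stop("unknown position label: ", label)
    pssm[i, ] <- pssm_row(omega, preferences[[label]], mass)
  }
  p1 <- position_index(spec, "P1")
  pssm[p1, ] <- 0
  pssm[p1, "D"] <- 1
  pssm
}

#' Default generating PSSM: DEVD-like core with graded flank signal
#'
#' Encodes the canonical caspase-3 preference — an acidic P4 (aspartate /
#' glutamate), glutamate at P3, a small hydrophobic P2, aspartate at P1 —
#' surrounded by flanking signal at every remaining position, emulating
#' substrate collections in which no window position is compositionally
#' neutral: a small-residue (G/S/A) preference at P1', notable signal at
#' P7, P6, P3', P4' and P5', and weak preferences elsewhere (P9, P8, P5,
#' P2').
#'
#' @inheritParams make_generating_pssm
#' @return positions x residues probability matrix.
#' @export
default_generating_pssm <- function(spec = window_spec(),
                                    omega = default_background()) {
  strong <- list(
    P4 = c(D = 5, E = 2, S = 1, T = 1),
    P3 = c(E = 5, D = 1, Q = 1),
    P2 = c(V = 4, P = 2, L = 1, T = 1),
    "P1'" = c(G = 3, S = 3, A = 2)
  )
  notable <- list(
    P7 = c(S = 2, D = 1, E = 1),
    P6 = c(E = 2, S = 1),
    "P3'" = c(E = 1, S = 1, G = 1),
    "P4'" = c(G = 1, S = 1),
    "P5'" = c(S = 1, G = 1, A = 1)
  )
  weak <- list(
    P9 = c(E = 1, S = 1),
    P8 = c(S = 1, A = 1),
    P5 = c(E = 1, D = 1),
    "P2'" = c(A = 1, G = 1)
  )
  pssm <- make_generating_pssm(strong, mass = 0.85, spec = spec, omega = omega)
  for (set in list(list(prefs = notable, mass = 0.35),
                   list(prefs = weak, mass = 0.2))) {
    sub <- make_generating_pssm(set$prefs, mass = set$mass, spec = spec,
                                omega = omega)
    for (label in names(set$prefs)) {
      i <- position_index(spec, label)
      pssm[i, ] <- sub[i, ]
    }
  }
  pssm
}

#' Generating PSSM with flank-only signal
#'
#' Informative positions only at P7, P1' and P3'; the P4..P2 core is pure
#' background (P1 remains aspartate, which negatives share). A model
#' restricted to the tetrapeptide window sees no signal in this data, while
#' the full P9-P5' window does — the basis of the window-size ordering
#' check.
#'
#' @inheritParams make_generating_pssm
#' @return positions x residues probability matrix.
#' @export
flank_signal_pssm <- function(spec = window_spec(),
                              omega = default_background()) {
  make_generating_pssm(list(
    P7 = c(S = 2, A = 1),
    "P1'" = c(G = 3, S = 2),
    "P3'" = c(E = 2, S = 1)
  ), mass = 0.85, spec = spec, omega = omega)
}

#' Configuration for the substrate simulator
#'
#' The defaults emulate the study conditions of a curated caspase-3
#' substrate collection: a few hundred substrate proteins of realistic
#' length, mostly one cleavage site each, a strongly specified DEVD-like
#' motif, and roughly half the sites carrying aspartate at P4. The
#' background aspartate rate (which sets the decoy density) is the
#' background frequency of D.
#'
#' @param n_proteins number of substrate proteins (default 250).
#' @param length_range uniform protein-length bounds (default c(200, 600)).
#' @param background residue frequencies for background sequence.
#' @param sites_per_protein named probability vector over site counts
#'   (default 85% one site, 15% two).
#' @param pssm generating PSSM (default [default_generating_pssm()]).
#' @param motif_strength mixing weight in `[0, 1]` between the generating
#'   PSSM and the background at each implanted position (default 0.9).
#' @param p4_d_fraction fraction of implanted sites drawn with aspartate at
#'   P4 (default 0.5); ignored when the window has no P4 position.
#' @param spec window geometry (default P9-P5').
#' @param seed RNG seed, mandatory.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 250, length_range = c(200, 600),
                              background = default_background(),
                              sites_per_protein = c("1" = 0.85, "2" = 0.15),
                              pssm = NULL, motif_strength = 0.9,
                              p4_d_fraction = 0.5, spec = window_spec(),
                              seed) {
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  background <- as_background(background)
  if (is.null(pssm)) pssm <- default_generating_pssm(spec, background)
  stopifnot(nrow(pssm) == spec$length, ncol(pssm) == 20,
            all(abs(rowSums(pssm) - 1) < 1e-9), all(pssm >= 0),
            motif_strength >= 0, motif_strength <= 1,
            p4_d_fraction >= 0, p4_d_fraction <= 1,
            length_range[1] >= spec$length, length_range[2] >= length_range[1],
            abs(sum(sites_per_protein) - 1) < 1e-9)
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 background = background,
                 sites_per_protein = sites_per_protein, pssm = pssm,
                 motif_strength = motif_strength,
                 p4_d_fraction = p4_d_fraction, spec = spec,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Uniform integer lengths; robust to lo == hi (sample() would otherwise
# treat a scalar as 1:n).
sample_lengths <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

# Sample one background sequence of length n.
sample_background_seq <- function(n, background) {
  paste(sample(AA_STANDARD, n, replace = TRUE, prob = background),
        collapse = "")
}

#' Simulate a background proteome (no implanted sites)
#'
#' Residues drawn independently from the background frequencies;
#' deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return a `protein_set`.
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  if (config$n_proteins == 0) {
    return(structure(stats::setNames(character(0), character(0)),
                     class = "protein_set", nonstandard = character(0)))
  }
  lens <- sample_lengths(config$length_range[1], config$length_range[2],
                         config$n_proteins)
  seqs <- vapply(lens, sample_background_seq, "", background = config$background)
  as_protein_set(stats::setNames(seqs, sprintf("SYN%05d", seq_len(config$n_proteins))))
}

# Draw one implanted window string from the implant distribution (rows of
# implant_distribution(config), precomputed by the caller).
sample_implant_window <- function(dist) {
  paste(vapply(seq_len(nrow(dist)), function(i) {
    sample(AA_STANDARD, 1, prob = dist[i, ])
  }, ""), collapse = "")
}

#' Exact per-position residue distribution of implanted windows
#'
#' The distribution actually sampled by the simulator: the generating PSSM
#' mixed with the background by `motif_strength`, with P1 forced to
#' aspartate. The P4 rule is itself strength-mixed: with weight
#' `motif_strength` the residue is aspartate with probability
#' `p4_d_fraction` (otherwise drawn from the PSSM's non-aspartate P4
#' alternatives, renormalised), with weight `1 - motif_strength` it is
#' background. At `motif_strength = 0` the implants are therefore exactly
#' background apart from the forced P1 aspartate, which negatives share —
#' a true null. Useful as the ground truth in parameter-recovery
#' experiments.
#'
#' @param config a [simulation_config()].
#' @return positions x residues probability matrix (rows sum to 1).
#' @export
implant_distribution <- function(config) {
  spec <- config$spec
  w <- config$motif_strength
  bg <- as.numeric(config$background)
  eff <- w * config$pssm +
    (1 - w) * matrix(bg, nrow = spec$length, ncol = 20, byrow = TRUE)
  dimnames(eff) <- list(spec$labels, AA_STANDARD)
  p4 <- position_index(spec, "P4")
  if (!is.na(p4)) {
    alt <- config$pssm[p4, ]; alt["D"] <- 0
    if (sum(alt) > 0) {
      alt <- alt / sum(alt)
    } else if (config$p4_d_fraction < 1) {
      stop("generating PSSM has no non-aspartate alternative at P4 ",
           "but p4_d_fraction < 1")
    }
    motif_p4 <- (1 - config$p4_d_fraction) * alt
    motif_p4["D"] <- config$p4_d_fraction
    eff[p4, ] <- w * motif_p4 + (1 - w) * bg
  }
  p1 <- position_index(spec, "P1")
  eff[p1, ] <- 0; eff[p1, "D"] <- 1
  eff
}

#' Simulate substrate proteins with implanted cleavage sites
#'
#' Background proteins receive 1+ cleavage windows drawn from the
#' generating PSSM (strength-mixed with the background) and overwritten at
#' non-overlapping placements that fulfil the length criterion. The truth
#' table records every aspartate in the final sequences: implanted P1 sites,
#' aspartates that fall inside an implanted window (attributed to the
#' implant), and background decoys.
#'
#' @param config a [simulation_config()].
#' @return list: `proteins` (a `protein_set`), `annotations` (data.frame
#'   protein_id, p1_position), `truth` (data.frame protein_id, position,
#'   is_site, origin in implanted_site / implant_flank / background).
#' @export
simulate_substrates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  spec <- config$spec
  dist <- implant_distribution(config)
  seqs <- character(config$n_proteins)
  ann <- list(); truth <- list()
  for (pi in seq_len(config$n_proteins)) {
    len <- sample_lengths(config$length_range[1], config$length_range[2], 1)
    seq_chars <- sample(AA_STANDARD, len, replace = TRUE,
                        prob = config$background)
    n_sites <- as.integer(sample(names(config$sites_per_protein), 1,
                                 prob = config$sites_per_protein))
    lo <- spec$upstream + 1L
    hi <- len - spec$downstream
    if (lo > hi) stop("protein too short for any site placement")
    placements <- integer(0)
    attempts <- 0
    while (length(placements) < n_sites && attempts < 1000) {
      cand <- sample(lo:hi, 1)
      if (all(abs(cand - placements) >= spec$length)) {
        placements <- c(placements, cand)
      }
      attempts <- attempts + 1
    }
    placements <- sort(placements)
    for (p in placements) {
      win <- strsplit(sample_implant_window(dist), "")[[1]]
      seq_chars[(p - spec$upstream):(p + spec$downstream)] <- win
    }
    seqs[pi] <- paste(seq_chars, collapse = "")
    id <- sprintf("SYN%05d", pi)
    ann[[pi]] <- data.frame(protein_id = id, p1_position = placements,
                            stringsAsFactors = FALSE)
    dpos <- which(seq_chars == "D")
    in_implant <- vapply(dpos, function(d) {
      any(d >= placements - spec$upstream & d <= placements + spec$downstream)
    }, logical(1))
    origin <- ifelse(dpos %in% placements, "implanted_site",
                     ifelse(in_implant, "implant_flank", "background"))
    truth[[pi]] <- data.frame(protein_id = id, position = dpos,
                              is_site = dpos %in% placements,
                              origin = origin, stringsAsFactors = FALSE)
  }
  proteins <- as_protein_set(stats::setNames(seqs, sprintf("SYN%05d",
                                                           seq_len(config$n_proteins))))
  list(proteins = proteins,
       annotations = do.call(rbind, ann),
       truth = do.call(rbind, truth))
}

#' Write a cleavage-annotation table as TSV
#'
#' @param annotations data.frame with protein_id, p1_position.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, c("protein_id", "p1_position")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
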