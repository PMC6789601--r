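# Synthetic feature samples and labeled outlier corpora for calibration
# and end-to-end testing without external structure downloads.

#' Specification of a synthetic feature sample
#'
#' A mixture of modes for one (residue type, feature); angular features
#' are drawn wrapped-normal (normal draws wrapped onto `[0, 360)`),
#' distances as truncated normals on `[0, Inf)`.
#'
#' @param residue_type three-letter code.
#' @param feature feature name.
#' @param modes numeric vector of mode centers (degrees or Angstrom).
#' @param sds per-mode standard deviations (recycled).
#' @param weights per-mode mixture weights, summing to 1 (recycled then
#'   renormalized).
#' @param n number of draws.
#' @param seed RNG seed.
#' @return object of class `hbos_sample_spec`.
#' @export
feature_sample_spec <- function(residue_type, feature, modes, sds,
                                weights = 1, n, seed = 1L) {
  k <- length(modes)
  sds <- rep_len(sds, k)
  weights <- rep_len(weights, k)
  weights <- weights / sum(weights)
  if (n <= 0) stop("n must be positive")
  structure(list(residue_type = residue_type, feature = feature,
                 modes = modes, sds = sds, weights = weights,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "hbos_sample_spec")
}

#' Draw synthetic feature values from a mixture
#'
#' @param spec an `hbos_sample_spec`.
#' @return numeric vector of length `spec$n`, reproducible by seed.
#' @export
sample_features <- function(spec) {
  stopifnot(inherits(spec, "hbos_sample_spec"))
  restore <- local_rng(spec$seed)
  on.exit(restore())
  comp <- sample.int(length(spec$modes), spec$n, replace = TRUE,
                     prob = spec$weights)
  x <- stats::rnorm(spec$n, spec$modes[comp], spec$sds[comp])
  if (spec$feature %in% ANGLE_FEATURES) {
    x %% 360
  } else {
    while (any(x < 0)) {
      x[x < 0] <- stats::rnorm(sum(x < 0), spec$modes[comp[x < 0]],
                               spec$sds[comp[x < 0]])
    }
    x
  }
}

# Canonical tight torsion modes used by the corpus generator: a single
# helix-like basin (phi ~ 297, psi ~ 318 on the 0-360 scale) and the
# common minus chi1 rotamer (~300), each with an 8-degree spread.
CORPUS_MODES <- list(phi = 297, psi = 318, chi1 = 300, sd = 8)

corpus_sequence <- function(rng_types, len) {
  paste(unname(AA_3TO1[rng_types[seq_len(len)]]), collapse = "")
}

#' Generate a labeled reference/probe corpus with planted outliers
#'
#' Builds a reference set of peptides whose torsions are drawn from tight
#' unimodal canonical modes, and a probe set from the same distribution in
#' which a few interior residues are planted at conformations 180 degrees
#' away from every reference mode, guaranteeing zero reference density in
#' their phi, psi and chi1 bins (and hence, by the floor rule, a component
#' score of `floor_score` each). Truth labels identify the planted
#' residues.
#'
#' All 18 scoreable residue types are cycled through deterministically so
#' every npdf table in a database built from the reference set is
#' populated.
#'
#' @param seed integer seed controlling all randomness.
#' @param n_reference number of reference peptides (default 200).
#' @param n_probe number of probe peptides (default 100).
#' @param n_planted number of planted outlier residues, at most one per
#'   probe peptide (default 20).
#' @param peptide_length residues per peptide (default 8).
#' @param mode_sd spread (degrees) of the torsion modes (default 8).
#' @return list with `reference` (list of structures), `probe` (list of
#'   structures), and `truth` (data frame `peptide`, `chain_id`, `resno`
#'   of planted residues).
#' @export
make_outlier_corpus <- function(seed = 1L, n_reference = 200,
                                n_probe = 100, n_planted = 20,
                                peptide_length = 8, mode_sd = 8) {
  if (n_planted > n_probe) stop("at most one planted residue per probe")
  restore <- local_rng(seed)
  on.exit(restore())
  m <- CORPUS_MODES
  draw_peptide <- function(plant_at = NA) {
    types <- sample(SCOREABLE_TYPES, peptide_length, replace = TRUE)
    phi <- stats::rnorm(peptide_length, m$phi, mode_sd) %% 360
    psi <- stats::rnorm(peptide_length, m$psi, mode_sd) %% 360
    chi1 <- stats::rnorm(peptide_length, m$chi1, mode_sd) %% 360
    if (!is.na(plant_at)) {
      phi[plant_at] <- (m$phi + 180) %% 360
      psi[plant_at] <- (m$psi + 180) %% 360
      chi1[plant_at] <- (m$chi1 + 180) %% 360
    }
    build_peptide(peptide_spec(paste(AA_3TO1[types], collapse = ""),
                               phi = phi, psi = psi, chi1 = chi1))
  }
  # seed every npdf table: the first ceiling(18*5/length) reference peptides
  # cycle through all 18 types deterministically
  reference <- vector("list", n_reference)
  cycle <- rep_len(SCOREABLE_TYPES, n_reference * peptide_length)
  for (i in seq_len(n_reference)) {
    if (i * peptide_length <= length(SCOREABLE_TYPES) * 3) {
      types <- cycle[((i - 1) * peptide_length + 1):(i * peptide_length)]
      phi <- stats::rnorm(peptide_length, m$phi, mode_sd) %% 360
      psi <- stats::rnorm(peptide_length, m$psi, mode_sd) %% 360
      chi1 <- stats::rnorm(peptide_length, m$chi1, mode_sd) %% 360
      reference[[i]] <- build_peptide(
        peptide_spec(paste(AA_3TO1[types], collapse = ""),
                     phi = phi, psi = psi, chi1 = chi1))
    } else {
      reference[[i]] <- draw_peptide()
    }
  }
  planted_in <- sort(sample.int(n_probe, n_planted))
  probe <- vector("list", n_probe)
  truth <- list()
  interior <- 2:(peptide_length - 1)
  for (i in seq_len(n_probe)) {
    if (i %in% planted_in) {
      pos <- sample(interior, 1)
      probe[[i]] <- draw_peptide(plant_at = pos)
      truth[[length(truth) + 1L]] <- data.frame(
        peptide = i, chain_id = "A", resno = pos)
    } else {
      probe[[i]] <- draw_peptide()
    }
  }
  list(reference = reference, probe = probe,
       truth = do.call(rbind, truth))
}
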