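# Geometry-controlled polypeptide fixtures.
#
# Chains are grown by sequential internal-coordinate extension (the NeRF
# construction): every atom is placed from a bond length, a plane angle and
# a torsion relative to three already-placed atoms, so target backbone and
# chi1 torsions are hit exactly (up to floating point), which is the whole
# point of the fixture builder.

# Idealized backbone geometry (Angstrom / degrees).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5, ca_cb = 1.530,
  # improper torsion C-N-CA-CB producing an L-amino acid (-122.8 deg)
  improper_cb = 237.2
)

#' Place an atom from internal coordinates (NeRF)
#'
#' Returns the position D such that |C-D| = `bond`, angle B-C-D = `angle`
#' and torsion A-B-C-D = `dihedral` (degrees).
#' @param a,b,c numeric length-3 positions of the reference atoms.
#' @param bond,angle,dihedral internal coordinates (Angstrom, degrees).
#' @return numeric length-3 position.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(c + m %*% d2)
}

#' Specification of a synthetic peptide
#'
#' Defines the sequence and target torsions for [build_peptide()]. Angle
#' vectors are recycled to the sequence length; `NA` entries fall back to
#' the defaults. phi of the first residue and psi of the last are not
#' realizable (no flanking residue) and are ignored.
#'
#' @param sequence one-letter amino-acid string (standard 20 codes).
#' @param phi,psi,omega,chi1 target torsions in degrees on the `[0, 360)`
#'   scale; defaults 300 / 320 / 180 (helix-like, trans peptide bond) and
#'   chi1 300.
#' @param jitter_sd standard deviation (Angstrom) of isotropic Gaussian
#'   noise added to every coordinate; 0 = exact geometry.
#' @param seed integer seed used when `jitter_sd > 0`.
#' @return object of class `hbos_peptide_spec`.
#' @export
peptide_spec <- function(sequence, phi = 300, psi = 320, omega = 180,
                         chi1 = 300, jitter_sd = 0, seed = 1L) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) == 0) stop("sequence must be non-empty")
  bad <- setdiff(seq1, names(AA_1TO3))
  if (length(bad)) stop("unsupported residue letter(s): ",
                        paste(unique(bad), collapse = ", "))
  n <- length(seq1)
  fill <- function(x, default) {
    x <- rep_len(as.numeric(x), n)
    x[is.na(x)] <- default
    if (any(x < 0 | x >= 360)) stop("target angles must lie in [0, 360)")
    x
  }
  structure(list(sequence = seq1, phi = fill(phi, 300),
                 psi = fill(psi, 320), omega = fill(omega, 180),
                 chi1 = fill(chi1, 300), jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "hbos_peptide_spec")
}

#' Build a synthetic polypeptide with prescribed torsions
#'
#' Grows one chain (id "A", residues numbered from 1) with idealized bond
#' lengths and angles; backbone phi/psi/omega and side-chain chi1 equal the
#' spec targets exactly, and side-chain atoms beyond the gamma atom use
#' idealized rotamer/planar torsions. Optional Gaussian coordinate jitter
#' (reproducible by seed) roughens the geometry for robustness tests.
#'
#' @param spec an `hbos_peptide_spec`.
#' @return an `hbos_structure` with a single chain.
#' @examples
#' s <- build_peptide(peptide_spec("AEA", phi = 252.3, psi = 134.5, chi1 = 286))
#' extract_features(s$chains[["A"]])
#' @export
build_peptide <- function(spec) {
  stopifnot(inherits(spec, "hbos_peptide_spec"))
  n <- length(spec$sequence)
  residues <- vector("list", n)
  g <- BB_GEOM
  # backbone of residue 1 in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * pi / 180
  C <- CA + g$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    type3 <- AA_1TO3[[spec$sequence[i]]]
    atoms <- list(N = N, CA = CA, C = C)
    # carbonyl O: trans to the next N, i.e. psi + 180 about CA-C
    atoms$O <- place_atom(N, CA, C, g$c_o, g$ang_ca_c_o,
                          (spec$psi[i] + 180) %% 360)
    if (type3 != "GLY") {
      atoms$CB <- place_atom(C, N, CA, g$ca_cb, g$ang_n_ca_cb, g$improper_cb)
      for (sa in SIDECHAIN_TOPOLOGY[[type3]]) {
        dih <- if (sa$dih_ref == "chi1") (spec$chi1[i] + sa$dih) %% 360 else sa$dih
        atoms[[sa$name]] <- place_atom(atoms[[sa$refs[1]]],
                                       atoms[[sa$refs[2]]],
                                       atoms[[sa$refs[3]]],
                                       sa$bond, sa$angle, dih)
      }
    }
    nm <- names(atoms)
    residues[[i]] <- new_residue(
      type3, i, "",
      data.frame(name = nm, element = element_from_name(nm),
                 x = vapply(atoms, `[[`, 0, 1),
                 y = vapply(atoms, `[[`, 0, 2),
                 z = vapply(atoms, `[[`, 0, 3),
                 stringsAsFactors = FALSE, row.names = NULL)
    )
    if (i < n) {
      N_next <- place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, spec$psi[i])
      CA_next <- place_atom(CA, C, N_next, g$n_ca, g$ang_c_n_ca, spec$omega[i])
      C_next <- place_atom(C, N_next, CA_next, g$ca_c, g$ang_n_ca_c,
                           spec$phi[i + 1])
      N <- N_next; CA <- CA_next; C <- C_next
    }
  }
  st <- new_structure("synthetic", list(new_chain("A", residues)),
                      NA_character_)
  if (spec$jitter_sd > 0) {
    st <- jitter_structure(st, spec$jitter_sd, spec$seed)
  }
  st
}

# Add iid Gaussian noise to every coordinate, reproducibly.
jitter_structure <- function(structure, sd, seed) {
  rng <- local_rng(seed)
  on.exit(rng())
  for (ci in seq_along(structure$chains)) {
    for (ri in seq_along(structure$chains[[ci]]$residues)) {
      a <- structure$chains[[ci]]$residues[[ri]]$atoms
      k <- nrow(a)
      a$x <- a$x + stats::rnorm(k, 0, sd)
      a$y <- a$y + stats::rnorm(k, 0, sd)
      a$z <- a$z + stats::rnorm(k, 0, sd)
      structure$chains[[ci]]$residues[[ri]]$atoms <- a
    }
  }
  structure
}

# Seed the RNG locally; returns a restore function for on.exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Write a structure as PDB text
#'
#' Emits standards-conformant fixed-column ATOM records with element
#' symbols, per-chain TER records and END. Coordinates round-trip through
#' [parse_structure()] to the 1e-3 Angstrom precision of the format.
#'
#' @param structure an `hbos_structure` with at least one atom.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "hbos_structure"))
  if (length(structure$chains) == 0) stop("structure has no chains")
  lines <- character(0)
  serial <- 0L
  for (ch in structure$chains) {
    if (length(ch$residues) == 0) next
    for (r in ch$residues) {
      a <- r$atoms
      if (any(abs(c(a$x, a$y, a$z)) > 9999.999)) {
        stop("coordinate exceeds PDB %8.3f column width")
      }
      for (k in seq_len(nrow(a))) {
        serial <- serial + 1L
        nm <- a$name[k]
        nm_field <- if (nchar(nm) >= 4) substr(nm, 1, 4)
                    else sprintf(" %-3s", nm)
        lines[length(lines) + 1L] <- sprintf(
          "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm_field, r$type3, ch$id, r$resno,
          ifelse(nzchar(r$icode), r$icode, " "),
          a$x[k], a$y[k], a$z[k], 1.00, 0.00, a$element[k])
      }
    }
    serial <- serial + 1L
    last <- ch$residues[[length(ch$residues)]]
    lines[length(lines) + 1L] <- sprintf(
      "TER   %5d      %3s %1s%4d", serial, last$type3, ch$id, last$resno)
  }
  if (serial == 0L) stop("structure has no atoms")
  lines[length(lines) + 1L] <- "END"
  writeLines(lines, path)
  invisible(path)
}
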