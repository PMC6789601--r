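# The five per-residue conformational features:
#   phi, psi   backbone torsions (degrees, 0-360 convention)
#   chi1       first side-chain torsion N-CA-CB-gamma
#   d_sidechain  CA to mass centroid of all heavy side-chain atoms (Angstrom)
#   d_block      CA to mass centroid of the distal block (Angstrom)
# Missing data is propagated as NA, never guessed.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Maximum peptide-bond C-N distance across which torsions are trusted;
# beyond this the chain is treated as broken.
PEPTIDE_BOND_MAX <- 2.0

#' Dihedral angle of four points on a 0-360 degree scale
#'
#' Standard signed IUPAC torsion computed with the atan2 construction, then
#' mapped from (-180, 180] to `[0, 360)` by adding 360 to negative values
#' (exactly 360 wraps to 0).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return angle in degrees in `[0, 360)`.
#' @examples
#' dihedral_deg(c(1,0,0), c(0,0,0), c(0,1,0), c(-1,1,0))  # 180 (trans)
#' @export
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1n <- sqrt(sum(n1^2))
  n2n <- sqrt(sum(n2^2))
  if (n1n < 1e-9 || n2n < 1e-9) {
    stop("degenerate geometry: collinear atom triple in dihedral")
  }
  m1 <- n1 / n1n
  m2 <- n2 / n2n
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * m2)
  y <- sum(cross3(m1, m2) * b2u)
  deg <- atan2(y, x) * 180 / pi
  if (deg < 0) deg <- deg + 360
  if (deg >= 360) deg <- deg - 360
  deg
}

# Residues count as peptide-adjacent when author numbering is consecutive
# (insertion codes share a number) and the C-N distance is bond-like.
residues_adjacent <- function(r_prev, r_cur) {
  gap <- r_cur$resno - r_prev$resno
  if (gap < 0 || gap > 1) return(FALSE)
  c_prev <- atom_xyz(r_prev, "C")
  n_cur <- atom_xyz(r_cur, "N")
  if (is.null(c_prev) || is.null(n_cur)) return(FALSE)
  sqrt(sum((n_cur - c_prev)^2)) <= PEPTIDE_BOND_MAX
}

#' Backbone torsion phi of a residue
#'
#' Dihedral C(prev)-N-CA-C. `NA` at the N-terminus, across a chain break
#' (author-numbering gap or peptide bond longer than 2 Angstrom), or when
#' any of the four atoms is absent.
#'
#' @param prev the preceding `hbos_residue`, or `NULL` at the N-terminus.
#' @param cur the target `hbos_residue`.
#' @return degrees in `[0, 360)` or `NA`.
#' @export
compute_phi <- function(prev, cur) {
  if (is.null(prev) || !residues_adjacent(prev, cur)) return(NA_real_)
  p <- list(atom_xyz(prev, "C"), atom_xyz(cur, "N"),
            atom_xyz(cur, "CA"), atom_xyz(cur, "C"))
  if (any(vapply(p, is.null, logical(1)))) return(NA_real_)
  dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' Backbone torsion psi of a residue
#'
#' Dihedral N-CA-C-N(next); `NA` at the C-terminus or across a chain break.
#'
#' @param cur the target `hbos_residue`.
#' @param nxt the following `hbos_residue`, or `NULL` at the C-terminus.
#' @return degrees in `[0, 360)` or `NA`.
#' @export
compute_psi <- function(cur, nxt) {
  if (is.null(nxt) || !residues_adjacent(cur, nxt)) return(NA_real_)
  p <- list(atom_xyz(cur, "N"), atom_xyz(cur, "CA"),
            atom_xyz(cur, "C"), atom_xyz(nxt, "N"))
  if (any(vapply(p, is.null, logical(1)))) return(NA_real_)
  dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' First side-chain torsion chi1
#'
#' Dihedral N-CA-CB-gamma where the gamma atom is residue-type specific
#' (CG by default; CG1 for ILE/VAL, OG for SER, OG1 for THR, SG for CYS).
#' GLY and ALA have no chi1 and return `NA`, as does any residue with a
#' required atom missing.
#'
#' @param cur the target `hbos_residue`.
#' @param blocks a block-definition table (see [default_block_table()]).
#' @return degrees in `[0, 360)` or `NA`.
#' @export
compute_chi1 <- function(cur, blocks = default_block_table()) {
  if (!cur$type3 %in% SCOREABLE_TYPES) return(NA_real_)
  gamma <- block_entry(blocks, cur$type3)$gamma_atom
  p <- list(atom_xyz(cur, "N"), atom_xyz(cur, "CA"),
            atom_xyz(cur, "CB"), atom_xyz(cur, gamma))
  if (any(vapply(p, is.null, logical(1)))) return(NA_real_)
  dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' Mass centroid of a set of atoms
#'
#' Mass-weighted mean position using conventional atomic masses. Hydrogens
#' are expected to have been excluded by the caller (deposited models
#' typically lack them).
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z`.
#' @return numeric length-3 vector.
#' @export
mass_centroid <- function(atoms) {
  if (is.null(atoms) || nrow(atoms) == 0) {
    stop("mass_centroid needs at least one atom")
  }
  m <- element_mass(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  as.numeric(colSums(xyz * m) / sum(m))
}

# Heavy side-chain atoms of a residue: anything not named as backbone, H excluded.
sidechain_atoms <- function(residue) {
  a <- residue$atoms
  a[!(a$name %in% BACKBONE_ATOMS) & a$element != "H", , drop = FALSE]
}

#' Side-chain size: CA to side-chain mass centroid
#'
#' Distance from CA to the mass centroid of all heavy side-chain atoms.
#' `NA` when the residue has no side-chain atoms or its side chain is
#' chemically incomplete (an expected heavy atom is absent), so partial
#' side chains never yield a deceptively short value.
#'
#' @param cur the target `hbos_residue`.
#' @return Angstrom or `NA`.
#' @export
compute_d_sidechain <- function(cur) {
  ca <- atom_xyz(cur, "CA")
  if (is.null(ca)) return(NA_real_)
  sc <- sidechain_atoms(cur)
  if (nrow(sc) == 0) return(NA_real_)
  expected <- sidechain_atom_names(cur$type3)
  if (length(expected) && !all(expected %in% sc$name)) return(NA_real_)
  cen <- mass_centroid(sc)
  sqrt(sum((cen - ca)^2))
}

#' Block length: CA to distal-block mass centroid
#'
#' Distance from CA to the mass centroid of the residue's distal block (the
#' terminal rigid group of the side chain, per the block table). `NA` when
#' any block atom is absent.
#'
#' @param cur the target `hbos_residue`.
#' @param blocks a block-definition table.
#' @return Angstrom or `NA`.
#' @export
compute_d_block <- function(cur, blocks = default_block_table()) {
  ca <- atom_xyz(cur, "CA")
  if (is.null(ca)) return(NA_real_)
  names_b <- block_entry(blocks, cur$type3)$distal_atoms
  a <- cur$atoms
  sel <- match(names_b, a$name)
  if (anyNA(sel)) return(NA_real_)
  cen <- mass_centroid(a[sel, , drop = FALSE])
  sqrt(sum((cen - ca)^2))
}

#' Extract the five features for every scoreable residue of a chain
#'
#' One row per standard residue excluding GLY and ALA (which have no chi1
#' and are not scored), in chain order. Unavailable values are `NA`.
#'
#' @param chain an `hbos_chain`.
#' @param blocks a block-definition table.
#' @return data frame with columns `chain_id`, `resno`, `icode`, `type3`,
#'   `phi`, `psi`, `chi1`, `d_sidechain`, `d_block`.
#' @examples
#' pep <- build_peptide(peptide_spec("AQEL", phi = 300, psi = 320))
#' extract_features(pep$chains[["A"]])
#' @export
extract_features <- function(chain, blocks = default_block_table()) {
  res <- chain$residues
  n <- length(res)
  rows <- list()
  for (i in seq_len(n)) {
    r <- res[[i]]
    if (!r$type3 %in% SCOREABLE_TYPES) next
    prev <- if (i > 1) res[[i - 1]] else NULL
    nxt <- if (i < n) res[[i + 1]] else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      chain_id = chain$id, resno = r$resno, icode = r$icode,
      type3 = r$type3,
      phi = compute_phi(prev, r),
      psi = compute_psi(r, nxt),
      chi1 = compute_chi1(r, blocks),
      d_sidechain = compute_d_sidechain(r),
      d_block = compute_d_block(r, blocks),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(chain_id = character(), resno = integer(),
                      icode = character(), type3 = character(),
                      phi = numeric(), psi = numeric(), chi1 = numeric(),
                      d_sidechain = numeric(), d_block = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
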