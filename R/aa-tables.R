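# Amino-acid lookup tables shared across the package.

#' @keywords internal
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @keywords internal
AA_1TO3 <- stats::setNames(names(AA_3TO1), unname(AA_3TO1))

# GLY and ALA carry no chi1 (no gamma atom) and are excluded from scoring.
#' @keywords internal
SCOREABLE_TYPES <- setdiff(names(AA_3TO1), c("GLY", "ALA"))

#' @keywords internal
FEATURE_NAMES <- c("phi", "psi", "chi1", "d_sidechain", "d_block")

#' @keywords internal
ANGLE_FEATURES <- c("phi", "psi", "chi1")

# Conventional atomic masses (u); hydrogens are excluded from centroids
# upstream but a mass is kept so stray H atoms fail loudly elsewhere, not here.
#' @keywords internal
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  SE = 78.971, P = 30.974
)

# Backbone atom names never counted as side chain.
#' @keywords internal
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Element symbol inferred from a PDB atom name
#'
#' Strips digits and primes and takes the leading letter(s). Handles the
#' standard-residue heavy atoms (C/N/O/S) used throughout the package.
#' @param name character vector of atom names (e.g. "CA", "OD1", "SG").
#' @return character vector of element symbols.
#' @keywords internal
element_from_name <- function(name) {
  core <- gsub("[0-9']", "", toupper(trimws(name)))
  ifelse(substr(core, 1, 2) == "SE", "SE", substr(core, 1, 1))
}

#' Mass of an element symbol
#' @keywords internal
element_mass <- function(element) {
  m <- ATOMIC_MASSES[toupper(element)]
  if (anyNA(m)) {
    stop("element(s) not resolvable to a standard atomic mass: ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
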