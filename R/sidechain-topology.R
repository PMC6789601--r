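# Idealized internal-coordinate recipes for side-chain construction.
#
# Each atom beyond CB is placed by the natural-extension reference frame
# (NeRF) from three previously placed atoms A-B-C: bond |C-D|, plane angle
# B-C-D, and torsion A-B-C-D. The gamma atom's torsion is the residue's
# chi1 target; later torsions are fixed at idealized rotamer/planar values.
# Bond lengths and angles follow standard amino-acid geometry tables to
# ~0.01 A / ~1 degree, which is ample for feature-extraction fixtures.

sc_atom <- function(name, refs, bond, angle, dih, dih_ref = "abs") {
  list(name = name, refs = refs, bond = bond, angle = angle,
       dih = dih, dih_ref = dih_ref)
}

#' @keywords internal
SIDECHAIN_TOPOLOGY <- list(
  ALA = list(),
  GLY = list(),
  SER = list(
    sc_atom("OG",  c("N", "CA", "CB"), 1.417, 110.8, 0, "chi1")),
  CYS = list(
    sc_atom("SG",  c("N", "CA", "CB"), 1.808, 114.4, 0, "chi1")),
  THR = list(
    sc_atom("OG1", c("N", "CA", "CB"), 1.433, 109.6, 0, "chi1"),
    sc_atom("CG2", c("N", "CA", "CB"), 1.521, 110.5, -122, "chi1")),
  VAL = list(
    sc_atom("CG1", c("N", "CA", "CB"), 1.527, 110.4, 0, "chi1"),
    sc_atom("CG2", c("N", "CA", "CB"), 1.527, 110.4, 122, "chi1")),
  ILE = list(
    sc_atom("CG1", c("N", "CA", "CB"), 1.530, 110.4, 0, "chi1"),
    sc_atom("CG2", c("N", "CA", "CB"), 1.521, 110.5, -122, "chi1"),
    sc_atom("CD1", c("CA", "CB", "CG1"), 1.513, 113.9, 180)),
  LEU = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.530, 116.3, 0, "chi1"),
    sc_atom("CD1", c("CA", "CB", "CG"), 1.521, 110.7, 180),
    sc_atom("CD2", c("CA", "CB", "CG"), 1.521, 110.7, 300)),
  ASP = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.516, 112.6, 0, "chi1"),
    sc_atom("OD1", c("CA", "CB", "CG"), 1.249, 118.4, 0),
    sc_atom("OD2", c("CA", "CB", "CG"), 1.249, 118.4, 180)),
  ASN = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.516, 112.6, 0, "chi1"),
    sc_atom("OD1", c("CA", "CB", "CG"), 1.231, 120.8, 0),
    sc_atom("ND2", c("CA", "CB", "CG"), 1.328, 116.4, 180)),
  GLU = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, 0, "chi1"),
    sc_atom("CD",  c("CA", "CB", "CG"), 1.516, 112.6, 180),
    sc_atom("OE1", c("CB", "CG", "CD"), 1.249, 118.4, 0),
    sc_atom("OE2", c("CB", "CG", "CD"), 1.249, 118.4, 180)),
  GLN = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, 0, "chi1"),
    sc_atom("CD",  c("CA", "CB", "CG"), 1.516, 112.6, 180),
    sc_atom("OE1", c("CB", "CG", "CD"), 1.231, 120.8, 0),
    sc_atom("NE2", c("CB", "CG", "CD"), 1.328, 116.4, 180)),
  MET = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, 0, "chi1"),
    sc_atom("SD",  c("CA", "CB", "CG"), 1.803, 112.7, 180),
    sc_atom("CE",  c("CB", "CG", "SD"), 1.791, 100.9, 180)),
  LYS = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, 0, "chi1"),
    sc_atom("CD",  c("CA", "CB", "CG"), 1.520, 111.3, 180),
    sc_atom("CE",  c("CB", "CG", "CD"), 1.508, 111.9, 180),
    sc_atom("NZ",  c("CG", "CD", "CE"), 1.486, 111.7, 180)),
  ARG = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.520, 114.1, 0, "chi1"),
    sc_atom("CD",  c("CA", "CB", "CG"), 1.520, 111.3, 180),
    sc_atom("NE",  c("CB", "CG", "CD"), 1.461, 112.0, 180),
    sc_atom("CZ",  c("CG", "CD", "NE"), 1.329, 124.2, 180),
    sc_atom("NH1", c("CD", "NE", "CZ"), 1.326, 120.0, 0),
    sc_atom("NH2", c("CD", "NE", "CZ"), 1.326, 120.0, 180)),
  HIS = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.497, 113.8, 0, "chi1"),
    sc_atom("ND1", c("CA", "CB", "CG"), 1.371, 122.7, 270),
    sc_atom("CD2", c("ND1", "CB", "CG"), 1.356, 131.2, 180),
    sc_atom("CE1", c("CB", "CG", "ND1"), 1.319, 109.3, 180),
    sc_atom("NE2", c("CG", "ND1", "CE1"), 1.330, 108.4, 0)),
  PHE = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.502, 113.8, 0, "chi1"),
    sc_atom("CD1", c("CA", "CB", "CG"), 1.384, 120.8, 90),
    sc_atom("CD2", c("CD1", "CB", "CG"), 1.384, 120.8, 180),
    sc_atom("CE1", c("CB", "CG", "CD1"), 1.382, 120.8, 180),
    sc_atom("CE2", c("CB", "CG", "CD2"), 1.382, 120.8, 180),
    sc_atom("CZ",  c("CG", "CD1", "CE1"), 1.380, 120.0, 0)),
  TYR = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.502, 113.8, 0, "chi1"),
    sc_atom("CD1", c("CA", "CB", "CG"), 1.384, 120.8, 90),
    sc_atom("CD2", c("CD1", "CB", "CG"), 1.384, 120.8, 180),
    sc_atom("CE1", c("CB", "CG", "CD1"), 1.382, 120.8, 180),
    sc_atom("CE2", c("CB", "CG", "CD2"), 1.382, 120.8, 180),
    sc_atom("CZ",  c("CG", "CD1", "CE1"), 1.380, 120.0, 0),
    sc_atom("OH",  c("CD1", "CE1", "CZ"), 1.376, 119.9, 180)),
  TRP = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.498, 113.6, 0, "chi1"),
    sc_atom("CD1", c("CA", "CB", "CG"), 1.365, 126.9, 90),
    sc_atom("CD2", c("CD1", "CB", "CG"), 1.433, 126.6, 180),
    sc_atom("NE1", c("CB", "CG", "CD1"), 1.374, 110.2, 180),
    sc_atom("CE2", c("CG", "CD1", "NE1"), 1.370, 109.0, 0),
    sc_atom("CE3", c("CD1", "CG", "CD2"), 1.398, 133.9, 180),
    sc_atom("CZ2", c("CD1", "NE1", "CE2"), 1.394, 130.4, 180),
    sc_atom("CZ3", c("CG", "CD2", "CE3"), 1.382, 118.8, 180),
    sc_atom("CH2", c("CD2", "CE3", "CZ3"), 1.368, 121.2, 0)),
  PRO = list(
    sc_atom("CG",  c("N", "CA", "CB"), 1.492, 104.5, 0, "chi1"),
    sc_atom("CD",  c("CA", "CB", "CG"), 1.503, 106.1, 330))
)

#' Expected heavy side-chain atom names of a residue type
#'
#' CB plus every atom in the idealized topology; used both by the builder
#' and by the side-chain completeness check in feature extraction.
#' @param type3 three-letter residue code.
#' @return character vector (empty for GLY).
#' @keywords internal
sidechain_atom_names <- function(type3) {
  topo <- SIDECHAIN_TOPOLOGY[[type3]]
  if (is.null(topo)) return(character(0))
  if (type3 == "GLY") return(character(0))
  c("CB", vapply(topo, `[[`, "", "name"))
}
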