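# The "distal block" of a side chain is its terminal rigid chemical group
# (e.g. the glutamate carboxylate, the leucine isopropyl, the aromatic ring).
# Block membership is data, not code: the default table ships as a TSV so it
# can be corrected or swapped without touching the implementation.

#' Load a distal-block definition table
#'
#' Each scoreable residue type (the 20 standard amino acids minus GLY and
#' ALA, which have no chi1) has one record giving the gamma atom that closes
#' the chi1 torsion (N-CA-CB-gamma) and the atom names of the distal block
#' whose mass centroid defines the block-length feature.
#'
#' @param path path to a TSV with columns `type3`, `gamma_atom`,
#'   `distal_atoms` (comma-separated atom names). Defaults to the table
#'   shipped with the package.
#' @return a data frame with one row per residue type and a list column
#'   `distal_atoms`; class `"hbos_blocks"`.
#' @examples
#' blocks <- default_block_table()
#' blocks[blocks$type3 == "LEU", ]
#' @export
load_block_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("type3", "gamma_atom", "distal_atoms")
  if (!all(need %in% names(tab))) {
    stop("block table must have columns: ", paste(need, collapse = ", "))
  }
  tab$type3 <- toupper(tab$type3)
  tab$distal_atoms <- lapply(strsplit(tab$distal_atoms, ","), trimws)
  if (anyDuplicated(tab$type3)) {
    stop("duplicate residue types in block table")
  }
  missing <- setdiff(SCOREABLE_TYPES, tab$type3)
  if (length(missing)) {
    stop("block table lacks definitions for: ", paste(missing, collapse = ", "))
  }
  if (any(lengths(tab$distal_atoms) == 0)) {
    stop("every block definition needs at least one distal atom")
  }
  class(tab) <- c("hbos_blocks", "data.frame")
  tab
}

#' @rdname load_block_table
#' @export
default_block_table <- function() {
  load_block_table(system.file("extdata", "block_definitions.tsv",
                               package = "hbosval", mustWork = TRUE))
}

#' @keywords internal
block_entry <- function(blocks, type3) {
  i <- match(type3, blocks$type3)
  if (is.na(i)) stop("no block definition for residue type ", type3)
  list(gamma_atom = blocks$gamma_atom[i],
       distal_atoms = blocks$distal_atoms[[i]])
}
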