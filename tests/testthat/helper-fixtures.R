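# Shared fixtures, built in code at test time.

# A reference DB in which every bin of every table has peak density 1,
# with selected tables overridden; lets scoring tests dial densities
# directly without building a corpus.
make_flat_db <- function(overrides = list()) {
  types <- hbosval:::SCOREABLE_TYPES
  feats <- hbosval:::FEATURE_NAMES
  tables <- list()
  for (t in types) {
    for (f in feats) {
      ang <- f %in% c("phi", "psi", "chi1")
      n <- if (ang) 72L else 200L
      key <- paste(t, f, sep = ".")
      dens <- overrides[[key]]
      if (is.null(dens)) dens <- rep(1, n)
      tables[[key]] <- list(residue_type = t, feature = f,
                            lower = 0, upper = if (ang) 360 else 10,
                            width = if (ang) 5 else 0.05,
                            sample_count = n, density = dens)
    }
  }
  structure(list(version = "1.0", metadata = list(corpus = "flat test db"),
                 tables = tables),
            class = "hbos_db")
}

# One extracted-feature row, defaulting to mid-bin values.
feature_row <- function(type3 = "GLN", phi = 182.5, psi = 182.5,
                        chi1 = 182.5, d_sidechain = 2.525, d_block = 3.025,
                        resno = 1L, chain_id = "A") {
  data.frame(chain_id = chain_id, resno = resno, icode = "",
             type3 = type3, phi = phi, psi = psi, chi1 = chi1,
             d_sidechain = d_sidechain, d_block = d_block,
             stringsAsFactors = FALSE)
}

# Small labeled corpus + db, built once and reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

small_corpus <- function() {
  if (is.null(.fixture_cache$corpus)) {
    .fixture_cache$corpus <- make_outlier_corpus(
      seed = 42, n_reference = 60, n_probe = 20, n_planted = 6)
  }
  .fixture_cache$corpus
}

small_corpus_db <- function() {
  if (is.null(.fixture_cache$db)) {
    .fixture_cache$db <- build_reference_from_structures(
      small_corpus()$reference, corpus_label = "small synthetic corpus")
  }
  .fixture_cache$db
}

# Hand-written PDB text: one 3-residue chain whose SER 2 CB carries two
# alternate locations (A at occupancy 0.6, B at 0.4), plus three waters.
write_altloc_fixture <- function(path) {
  base <- build_peptide(peptide_spec("ASA"))
  write_pdb(base, path)
  lines <- readLines(path)
  # give the SER CB two conformers: keep original position as altloc A,
  # add a shifted altloc B with lower occupancy
  cb_i <- grep("^ATOM.{8} CB  SER", lines)
  stopifnot(length(cb_i) == 1)
  a_line <- lines[cb_i]
  substr(a_line, 17, 17) <- "A"
  b_line <- a_line
  substr(b_line, 7, 11) <- sprintf("%5d", 801L)
  substr(b_line, 17, 17) <- "B"
  x <- as.numeric(substr(a_line, 31, 38)) + 0.5
  substr(b_line, 31, 38) <- sprintf("%8.3f", x)
  substr(a_line, 55, 60) <- "  0.60"
  substr(b_line, 55, 60) <- "  0.40"
  waters <- sprintf(
    "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
    900 + 1:3, 100 + 1:3, 20 + 1:3, 20, 20)
  lines <- append(lines, waters, after = length(lines) - 1)
  lines[cb_i] <- a_line
  lines <- append(lines, b_line, after = cb_i)
  writeLines(lines, path)
  invisible(path)
}

# Random rigid-body transform applied to every atom of a structure.
rigid_transform <- function(structure, seed = 1) {
  set.seed(seed)
  ang <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                 sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  rot <- rx %*% ry %*% rz
  shift <- stats::runif(3, -20, 20)
  for (ci in seq_along(structure$chains)) {
    for (ri in seq_along(structure$chains[[ci]]$residues)) {
      a <- structure$chains[[ci]]$residues[[ri]]$atoms
      xyz <- t(rot %*% t(as.matrix(a[, c("x", "y", "z")]))) +
        matrix(shift, nrow(a), 3, byrow = TRUE)
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      structure$chains[[ci]]$residues[[ri]]$atoms <- a
    }
  }
  structure
}
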