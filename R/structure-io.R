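# Coordinate ingestion: parse PDB/mmCIF into a light residue hierarchy and
# remove near-duplicate (NCS) chains before feature extraction.

new_residue <- function(type3, resno, icode, atoms) {
  structure(list(type3 = type3, resno = as.integer(resno),
                 icode = icode, atoms = atoms),
            class = "hbos_residue")
}

new_chain <- function(id, residues) {
  structure(list(id = id, residues = residues), class = "hbos_chain")
}

new_structure <- function(id, chains, source_path = NA_character_,
                          skipped = data.frame()) {
  ids <- vapply(chains, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("chain ids must be unique within a model")
  structure(list(id = id, chains = stats::setNames(chains, ids),
                 source_path = source_path, skipped = skipped),
            class = "hbos_structure")
}

#' Coordinates of a named atom in a residue
#' @param residue an `hbos_residue`.
#' @param name atom name, e.g. `"CA"`.
#' @return numeric length-3 vector, or `NULL` if the atom is absent.
#' @export
atom_xyz <- function(residue, name) {
  i <- match(name, residue$atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(residue$atoms[i, c("x", "y", "z")])
}

#' One-letter sequence of a chain
#' @param chain an `hbos_chain`.
#' @return single character string over the 20 standard one-letter codes.
#' @export
chain_sequence <- function(chain) {
  paste(AA_3TO1[vapply(chain$residues, `[[`, "", "type3")], collapse = "")
}

#' @export
print.hbos_structure <- function(x, ...) {
  cat("<hbos_structure>", x$id, "\n")
  for (ch in x$chains) {
    cat("  chain", ch$id, ":", length(ch$residues), "residues\n")
  }
  if (nrow(x$skipped)) {
    cat("  skipped non-standard residues:", nrow(x$skipped), "\n")
  }
  invisible(x)
}

#' @export
print.hbos_chain <- function(x, ...) {
  cat("<hbos_chain>", x$id, ":", length(x$residues), "residues\n")
  invisible(x)
}

#' Parse a coordinate file into a residue hierarchy
#'
#' Reads a PDB (or mmCIF) file and returns only the polymer amino-acid
#' content of one model: waters, ligands and nucleic acids are dropped, and
#' non-standard amino-acid residues (e.g. MSE) are skipped and reported in
#' the `skipped` field rather than silently remapped. For alternate
#' locations the highest-occupancy conformer is kept, ties resolved in file
#' order.
#'
#' @param path path to a PDB or mmCIF file.
#' @param model_index 1-based model number for multi-model files.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @return an `hbos_structure`: a list of chains, each an ordered list of
#'   residues holding an atom table (`name`, `element`, `x`, `y`, `z`).
#' @examples
#' pep <- build_peptide(peptide_spec("QEL"))
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(pep, f)
#' parse_structure(f)
#' @export
parse_structure <- function(path, model_index = 1L,
                            format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") {
      bio3d::read.cif(path, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, multi = TRUE, rm.insert = FALSE,
                      rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model", if (n_models > 1) "s", ")")
  }
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("could not parse ", path, ": no coordinate records found",
         call. = FALSE)
  }
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else as.numeric(pdb$xyz)
  at$x <- xyz[seq(1, by = 3, length.out = nrow(at))]
  at$y <- xyz[seq(2, by = 3, length.out = nrow(at))]
  at$z <- xyz[seq(3, by = 3, length.out = nrow(at))]

  poly <- at[at$type == "ATOM", , drop = FALSE]
  is_std <- poly$resid %in% names(AA_3TO1)
  # residues that look peptide-like but are not standard: report, don't score
  skipped <- unique(poly[!is_std, c("resid", "chain", "resno"), drop = FALSE])
  poly <- poly[is_std, , drop = FALSE]
  if (nrow(poly) == 0) {
    return(new_structure(basename(path), list(), path, skipped))
  }
  poly$icode <- ifelse(is.na(poly$insert) | poly$insert == "", "", poly$insert)
  poly$elem <- ifelse(is.na(poly$elesy) | poly$elesy == "",
                      element_from_name(poly$elety), toupper(poly$elesy))
  poly$occ <- ifelse(is.na(poly$o), 1, poly$o)

  chains <- list()
  for (ch_id in unique(poly$chain)) {
    ca <- poly[poly$chain == ch_id, , drop = FALSE]
    rkey <- paste(ca$resno, ca$icode, sep = "|")
    residues <- lapply(unique(rkey), function(k) {
      ra <- ca[rkey == k, , drop = FALSE]
      # alternate locations: per atom name keep highest occupancy, first wins ties
      keep <- unlist(lapply(split(seq_len(nrow(ra)), ra$elety),
                            function(ix) ix[which.max(ra$occ[ix])]))
      ra <- ra[sort(keep), , drop = FALSE]
      atoms <- data.frame(name = ra$elety, element = ra$elem,
                          x = ra$x, y = ra$y, z = ra$z,
                          stringsAsFactors = FALSE)
      if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
        stop("non-finite coordinates in residue ", ra$resid[1], " ",
             ra$resno[1], " of chain ", ch_id)
      }
      new_residue(ra$resid[1], ra$resno[1], ra$icode[1], atoms)
    })
    chains[[length(chains) + 1L]] <- new_chain(ch_id, residues)
  }
  new_structure(sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                    ignore.case = TRUE),
                chains, path, skipped)
}

#' Global-alignment sequence identity of two chains
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and a
#' simple affine gap penalty; identity is the number of identical aligned
#' positions divided by the alignment length (including gap columns). This
#' is the conventional reading of "sequence similarity" for
#' non-crystallographic-symmetry chain removal.
#'
#' @param a,b one-letter amino-acid sequences (non-empty strings).
#' @return identity fraction in `[0, 1]`.
#' @examples
#' sequence_identity("ACDEF", "ACDEF")  # 1
#' sequence_identity("AAAA", "CCCC")    # 0
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  letters20 <- c(unname(AA_3TO1), "X")
  sm <- diag(1, length(letters20))
  dimnames(sm) <- list(letters20, letters20)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 0.5
  )
  n_match <- Biostrings::nmatch(aln)
  aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  n_match / aln_len
}

#' Remove near-duplicate chains from a structure
#'
#' Chains are scanned in file order; a chain is dropped when its global
#' sequence identity to any previously kept chain reaches the threshold.
#' This removes non-crystallographic-symmetry copies so a reference corpus
#' is not dominated by repeated identical chains.
#'
#' @param structure an `hbos_structure`.
#' @param threshold identity fraction at or above which a chain is
#'   considered a duplicate (default 0.95).
#' @return list of kept `hbos_chain` objects, original order preserved.
#' @export
deduplicate_chains <- function(structure, threshold = 0.95) {
  chains <- unname(structure$chains)
  chains <- Filter(function(ch) length(ch$residues) > 0, chains)
  if (length(chains) == 0) return(list())
  kept <- list(chains[[1]])
  kept_seqs <- chain_sequence(chains[[1]])
  for (ch in chains[-1]) {
    s <- chain_sequence(ch)
    dup <- any(vapply(kept_seqs,
                      function(ks) sequence_identity(ks, s) >= threshold,
                      logical(1)))
    if (!dup) {
      kept[[length(kept) + 1L]] <- ch
      kept_seqs <- c(kept_seqs, s)
    }
  }
  kept
}
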