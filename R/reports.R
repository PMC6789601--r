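# Report writers: tabular outlier reports (TSV/JSON) mirroring the
# validation-GUI column layout, and a Chimera attribute file so any
# visualization platform can color residues by HBOS total.

#' Tabulate residue scores as an outlier report
#'
#' Columns follow the validation-report convention: `Residue`, `Index`,
#' `B-Dist` (block-length score), `S-Dist` (side-chain-size score),
#' `Phi`, `Psi`, `Chi_1`, `Total`, `Outlier` and `Flagged` (features whose
#' individual score exceeds the flag threshold, the report analogue of the
#' GUI's red highlight).
#'
#' @param scores an `hbos_scores` data frame from [score_chain()].
#' @param mode `"outliers"` (default) restricts rows to labeled outliers;
#'   `"full"` keeps every scored residue.
#' @param include_unscored also keep unscored residues (full mode only).
#' @return data frame with the report columns.
#' @export
score_report <- function(scores, mode = c("outliers", "full"),
                         include_unscored = FALSE) {
  mode <- match.arg(mode)
  rows <- if (mode == "outliers") scores[scores$is_outlier, , drop = FALSE]
          else if (include_unscored) scores
          else scores[scores$scored, , drop = FALSE]
  rep <- data.frame(
    Residue = rows$type3,
    Index = paste0(rows$resno, rows$icode),
    Chain = rows$chain_id,
    `B-Dist` = rows$score_d_block,
    `S-Dist` = rows$score_d_sidechain,
    Phi = rows$score_phi,
    Psi = rows$score_psi,
    Chi_1 = rows$score_chi1,
    Total = rows$total,
    Outlier = rows$is_outlier,
    Flagged = rows$flagged_features,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  rownames(rep) <- NULL
  rep
}

#' Write an outlier report as TSV
#'
#' Score columns are printed with two decimals; the JSON writer keeps full
#' precision.
#' @param report data frame from [score_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.2f", x))
  out[num] <- lapply(out[num], function(x) ifelse(x == "NA", "", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an outlier report as JSON
#' @param report data frame from [score_report()].
#' @param path output path.
#' @param metadata optional named list recorded under `"metadata"`.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, metadata = list()) {
  jsonlite::write_json(list(metadata = metadata, residues = report),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Export residue HBOS totals as a Chimera attribute file
#'
#' Writes the documented Chimera "attribute assignment" format mapping
#' residue specifiers (`:resno.chain`) to HBOS totals, so residues can be
#' colored by score in Chimera or any tool reading the format. Unscored
#' residues are omitted.
#'
#' @param scores an `hbos_scores` data frame.
#' @param path output path.
#' @param attribute attribute name (default `"hbosTotal"`).
#' @return `path`, invisibly.
#' @export
write_chimera_attributes <- function(scores, path, attribute = "hbosTotal") {
  rows <- scores[scores$scored, , drop = FALSE]
  lines <- c(
    paste0("attribute: ", attribute),
    "match mode: 1-to-1",
    "recipient: residues",
    sprintf("\t:%s%s.%s\t%.6f", rows$resno, rows$icode, rows$chain_id,
            rows$total)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a Chimera attribute file
#'
#' Inverse of [write_chimera_attributes()]; mainly a serialization check.
#' @param path attribute file path.
#' @return data frame with columns `spec` and `value`.
#' @export
read_chimera_attributes <- function(path) {
  lines <- readLines(path)
  rows <- grep("^\t", lines, value = TRUE)
  parts <- strsplit(sub("^\t", "", rows), "\t")
  data.frame(spec = vapply(parts, `[[`, "", 1),
             value = as.numeric(vapply(parts, `[[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Build a reference database from files on disk (command form)
#'
#' The programmatic core of the `build-ref` command-line verb: collects
#' the coordinate files, builds the database and writes it as JSON.
#'
#' @param inputs directory containing `.pdb`/`.cif` files, or an explicit
#'   character vector of file paths.
#' @param out output path for the database JSON.
#' @param distance_cap,dedup_threshold,corpus_label see [build_reference()].
#' @param dedup set `FALSE` to skip NCS chain removal.
#' @param verbose print per-corpus progress to standard error.
#' @return the `hbos_db`, invisibly.
#' @export
cmd_build_ref <- function(inputs, out, distance_cap = 10, dedup = TRUE,
                          dedup_threshold = 0.95,
                          corpus_label = "reference corpus",
                          verbose = FALSE) {
  paths <- if (length(inputs) == 1 && dir.exists(inputs)) {
    list.files(inputs, pattern = "\\.(pdb|ent|cif|mmcif)$",
               full.names = TRUE, ignore.case = TRUE)
  } else {
    inputs
  }
  if (length(paths) == 0) stop("no coordinate files found in input")
  db <- build_reference(paths, distance_cap = distance_cap,
                        dedup_threshold = if (dedup) dedup_threshold else NA,
                        corpus_label = corpus_label)
  save_db(db, out)
  if (verbose) {
    message("built reference DB from ", db$metadata$n_files, " file(s), ",
            db$metadata$n_residues, " residues -> ", out)
  }
  invisible(db)
}

#' Score a structure against a reference database (command form)
#'
#' The programmatic core of the `score` command-line verb: loads the
#' database and the structure, scores one chain and writes the requested
#' report file(s).
#'
#' @param input path to the PDB/mmCIF file to validate.
#' @param db path to a reference-database JSON (or an `hbos_db`).
#' @param chain chain id; defaults to the first chain in the file.
#' @param threshold,flag_threshold outlier / per-feature flag thresholds.
#' @param format `"tsv"`, `"json"` or `"both"`.
#' @param mode `"outliers"` or `"full"` report rows.
#' @param out output path stem; `.tsv`/`.json` appended as needed. `NULL`
#'   writes nothing and just returns the scores.
#' @param chimera_attr optional path for a Chimera attribute file.
#' @return the `hbos_scores` data frame, invisibly.
#' @export
cmd_score <- function(input, db, chain = NULL, threshold = 10,
                      flag_threshold = 2, format = c("tsv", "json", "both"),
                      mode = c("outliers", "full"), out = NULL,
                      chimera_attr = NULL) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!inherits(db, "hbos_db")) db <- load_db(db)
  st <- parse_structure(input)
  if (length(st$chains) == 0) stop("no amino-acid chains in ", input)
  if (is.null(chain)) chain <- names(st$chains)[1]
  if (!chain %in% names(st$chains)) {
    stop("chain '", chain, "' not found; available: ",
         paste(names(st$chains), collapse = ", "))
  }
  params <- scoring_params(outlier_threshold = threshold,
                           flag_threshold = flag_threshold)
  scores <- score_chain(st$chains[[chain]], db, params)
  report <- score_report(scores, mode = mode,
                         include_unscored = mode == "full")
  meta <- list(input = input, chain = chain,
               outlier_threshold = threshold,
               flag_threshold = flag_threshold,
               db_corpus = db$metadata$corpus)
  if (!is.null(out)) {
    stem <- sub("\\.(tsv|json)$", "", out)
    if (format %in% c("tsv", "both")) {
      write_report_tsv(report, paste0(stem, ".tsv"))
    }
    if (format %in% c("json", "both")) {
      write_report_json(report, paste0(stem, ".json"), metadata = meta)
    }
  }
  if (!is.null(chimera_attr)) {
    write_chimera_attributes(scores, chimera_attr)
  }
  invisible(scores)
}
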