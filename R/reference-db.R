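# The HBOS reference database: per (residue type, feature) histogram
# densities normalized by their highest peak ("npdfs"). 18 scoreable types
# x 5 features = 90 tables. Angles use 5-degree bins over [0, 360); the two
# distances use 0.05-Angstrom bins over [0, cap).

#' Bin specification for one feature domain
#'
#' Half-open bins `[edge, edge + width)`. The bin count must tile the
#' domain exactly.
#'
#' @param lower,upper domain limits (degrees or Angstrom).
#' @param width bin width; 5 degrees for angles, 0.05 Angstrom for
#'   distances by convention.
#' @return object of class `hbos_binspec`.
#' @export
bin_spec <- function(lower, upper, width) {
  if (width <= 0 || upper <= lower) stop("invalid bin specification")
  count <- (upper - lower) / width
  if (abs(count - round(count)) > 1e-9) {
    stop("bin width must tile [lower, upper] exactly")
  }
  structure(list(lower = lower, upper = upper, width = width,
                 count = as.integer(round(count))),
            class = "hbos_binspec")
}

angle_bins <- function(width = 5) bin_spec(0, 360, width)
distance_bins <- function(cap = 10, width = 0.05) bin_spec(0, cap, width)

#' Bin index of a feature value
#'
#' `floor((value - lower) / width)` with half-open bins, returned 1-based.
#' Angular values wrap modulo the domain (360 maps to the first bin);
#' out-of-domain distance values return `NA` ("out of range", treated as
#' unobserved by lookup).
#'
#' @param value numeric feature value(s).
#' @param bins an `hbos_binspec`.
#' @param wrap `TRUE` for angular features.
#' @return integer bin index in `1..count`, or `NA` if out of range.
#' @export
bin_index <- function(value, bins, wrap = FALSE) {
  v <- as.numeric(value)
  if (wrap) {
    span <- bins$upper - bins$lower
    v <- bins$lower + ((v - bins$lower) %% span)
  }
  idx <- floor((v - bins$lower) / bins$width) + 1L
  idx[v < bins$lower | v >= bins$upper] <- NA_integer_
  idx[is.na(v)] <- NA_integer_
  as.integer(idx)
}

#' Peak-normalize histogram counts
#'
#' Divides a count vector by its maximum so the highest peak equals 1
#' exactly; an all-zero histogram stays all-zero.
#'
#' @param counts non-negative numeric vector.
#' @return density vector in `[0, 1]`.
#' @export
normalize_to_peak <- function(counts) {
  if (any(counts < 0)) stop("negative histogram counts")
  m <- max(counts)
  if (m == 0) return(as.numeric(counts))
  counts / m
}

table_key <- function(type3, feature) paste(type3, feature, sep = ".")

# A mutable accumulator of raw counts for all 90 (type, feature) histograms.
new_histogram_set <- function(distance_cap = 10, angle_width = 5,
                              distance_width = 0.05) {
  env <- new.env(parent = emptyenv())
  env$bins <- list(angle = angle_bins(angle_width),
                   distance = distance_bins(distance_cap, distance_width))
  env$counts <- list()
  for (t in SCOREABLE_TYPES) {
    for (f in FEATURE_NAMES) {
      b <- if (f %in% ANGLE_FEATURES) env$bins$angle else env$bins$distance
      env$counts[[table_key(t, f)]] <- numeric(b$count)
    }
  }
  env$n_residues <- 0L
  env
}

#' Accumulate feature observations into a histogram set
#'
#' Every non-missing feature value increments the matching (residue type,
#' feature) histogram by one; `NA` values and out-of-range distances
#' contribute nothing.
#'
#' @param features data frame from [extract_features()].
#' @param hset histogram accumulator from the reference builder.
#' @return `hset`, invisibly (updated in place).
#' @keywords internal
accumulate <- function(features, hset) {
  for (i in seq_len(nrow(features))) {
    t <- features$type3[i]
    if (!t %in% SCOREABLE_TYPES) next
    for (f in FEATURE_NAMES) {
      v <- features[[f]][i]
      if (is.na(v)) next
      b <- if (f %in% ANGLE_FEATURES) hset$bins$angle else hset$bins$distance
      k <- bin_index(v, b, wrap = f %in% ANGLE_FEATURES)
      if (is.na(k)) next
      key <- table_key(t, f)
      hset$counts[[key]][k] <- hset$counts[[key]][k] + 1
    }
  }
  hset$n_residues <- hset$n_residues + nrow(features)
  invisible(hset)
}

finalize_db <- function(hset, metadata = list()) {
  tables <- list()
  for (t in SCOREABLE_TYPES) {
    for (f in FEATURE_NAMES) {
      key <- table_key(t, f)
      counts <- hset$counts[[key]]
      b <- if (f %in% ANGLE_FEATURES) hset$bins$angle else hset$bins$distance
      tables[[key]] <- list(
        residue_type = t, feature = f,
        lower = b$lower, upper = b$upper, width = b$width,
        sample_count = as.integer(sum(counts)),
        density = normalize_to_peak(counts)
      )
    }
  }
  structure(list(version = DB_SCHEMA_VERSION, metadata = metadata,
                 tables = tables),
            class = "hbos_db")
}

DB_SCHEMA_VERSION <- "1.0"

#' @export
print.hbos_db <- function(x, ...) {
  ns <- vapply(x$tables, `[[`, 0L, "sample_count")
  cat("<hbos_db>", length(x$tables), "npdf tables,",
      sum(ns[seq(1, length(ns), by = 5)]), "reference residues\n")
  if (!is.null(x$metadata$corpus)) cat("  corpus:", x$metadata$corpus, "\n")
  invisible(x)
}

#' Build an HBOS reference database from coordinate files
#'
#' End-to-end reference construction: parse each file, drop
#' near-duplicate (NCS) chains, extract the five features from every
#' scoreable residue, accumulate the 90 histograms and peak-normalize
#' them. Files that fail to parse are skipped with a warning so one bad
#' entry cannot abort a corpus build.
#'
#' @param paths character vector of PDB/mmCIF file paths.
#' @param distance_cap upper limit (Angstrom) of the distance-feature
#'   domain; values beyond it are treated as unobserved (default 10).
#' @param angle_width,distance_width bin widths (5 degrees / 0.05 Angstrom).
#' @param dedup_threshold identity at which chains are dropped as NCS
#'   copies; `NA` disables deduplication.
#' @param blocks block-definition table.
#' @param corpus_label free-text provenance recorded in the metadata.
#' @return an `hbos_db`.
#' @export
build_reference <- function(paths, distance_cap = 10, angle_width = 5,
                            distance_width = 0.05, dedup_threshold = 0.95,
                            blocks = default_block_table(),
                            corpus_label = "unlabeled corpus") {
  if (length(paths) == 0) stop("no input files")
  hset <- new_histogram_set(distance_cap, angle_width, distance_width)
  n_files <- 0L
  for (p in paths) {
    st <- tryCatch(parse_structure(p), error = function(e) {
      warning("skipping ", p, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(st)) next
    chains <- if (is.na(dedup_threshold)) unname(st$chains)
              else deduplicate_chains(st, dedup_threshold)
    for (ch in chains) accumulate(extract_features(ch, blocks), hset)
    n_files <- n_files + 1L
  }
  if (hset$n_residues == 0L) {
    stop("empty corpus: no scoreable residues found in ", length(paths),
         " file(s)")
  }
  finalize_db(hset, metadata = list(
    corpus = corpus_label, n_files = n_files,
    n_residues = hset$n_residues,
    distance_cap = distance_cap, angle_width = angle_width,
    distance_width = distance_width, dedup_threshold = dedup_threshold,
    built = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  ))
}

#' Build a reference database directly from structures in memory
#'
#' Same accumulation as [build_reference()] but over already-parsed
#' structures (e.g. synthetic peptides), skipping file I/O.
#' @param structures list of `hbos_structure` objects.
#' @inheritParams build_reference
#' @return an `hbos_db`.
#' @export
build_reference_from_structures <- function(structures, distance_cap = 10,
                                            angle_width = 5,
                                            distance_width = 0.05,
                                            dedup_threshold = NA,
                                            blocks = default_block_table(),
                                            corpus_label = "in-memory corpus") {
  hset <- new_histogram_set(distance_cap, angle_width, distance_width)
  for (st in structures) {
    chains <- if (is.na(dedup_threshold)) unname(st$chains)
              else deduplicate_chains(st, dedup_threshold)
    for (ch in chains) accumulate(extract_features(ch, blocks), hset)
  }
  if (hset$n_residues == 0L) stop("empty corpus: no scoreable residues")
  finalize_db(hset, metadata = list(
    corpus = corpus_label, n_files = length(structures),
    n_residues = hset$n_residues, distance_cap = distance_cap,
    angle_width = angle_width, distance_width = distance_width,
    dedup_threshold = dedup_threshold,
    built = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  ))
}

#' Look up the npdf density for a feature value
#'
#' Reads the peak-normalized density of the bin containing `value` from
#' the (residue type, feature) table. Out-of-range distances return 0
#' (unobserved), which the scoring floor then penalizes.
#'
#' @param db an `hbos_db`.
#' @param residue_type three-letter code (one of the 18 scoreable types).
#' @param feature one of `"phi"`, `"psi"`, `"chi1"`, `"d_sidechain"`,
#'   `"d_block"`.
#' @param value feature value (degrees or Angstrom).
#' @return density in `[0, 1]`.
#' @export
lookup_npdf <- function(db, residue_type, feature, value) {
  tab <- db$tables[[table_key(residue_type, feature)]]
  if (is.null(tab)) {
    stop("no npdf table for (", residue_type, ", ", feature, ")")
  }
  b <- bin_spec(tab$lower, tab$upper, tab$width)
  k <- bin_index(value, b, wrap = feature %in% ANGLE_FEATURES)
  if (is.na(k)) return(0)
  tab$density[k]
}

#' Serialize / load an HBOS reference database
#'
#' The database is stored as a single JSON document carrying the schema
#' version, build metadata and all 90 tables with full-precision
#' densities; `load_db(save_db(db))` is lossless. Loading validates the
#' schema version and table completeness so a truncated or foreign file
#' fails loudly instead of corrupting scores.
#'
#' @param db an `hbos_db`.
#' @param path file path for the JSON document.
#' @return `save_db` returns `path` invisibly; `load_db` returns an
#'   `hbos_db`.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "hbos_db"))
  jsonlite::write_json(
    list(version = db$version, metadata = db$metadata,
         tables = unname(db$tables)),
    path, auto_unbox = TRUE, digits = I(17), null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname save_db
#' @export
load_db <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop("cannot read reference DB ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(raw$version) || !identical(as.character(raw$version),
                                         DB_SCHEMA_VERSION)) {
    stop("reference DB schema version mismatch: found ",
         if (is.null(raw$version)) "<none>" else raw$version,
         ", expected ", DB_SCHEMA_VERSION)
  }
  tables <- list()
  for (tab in raw$tables) {
    tab$density <- as.numeric(tab$density)
    tab$sample_count <- as.integer(tab$sample_count)
    tables[[table_key(tab$residue_type, tab$feature)]] <- tab
  }
  expected <- as.vector(outer(SCOREABLE_TYPES, FEATURE_NAMES, table_key))
  absent <- setdiff(expected, names(tables))
  if (length(absent)) {
    stop("reference DB incomplete; missing tables: ",
         paste(absent, collapse = ", "))
  }
  structure(list(version = DB_SCHEMA_VERSION, metadata = raw$metadata,
                 tables = tables),
            class = "hbos_db")
}
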