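# HBOS scoring: per feature, score = log(1 / npdf(value)); densities below
# a floor (default 0.001) get a fixed penalty (default 5) so unobserved
# bins cannot produce infinities. A residue's score is the sum over its
# five features; totals above the outlier threshold (default 10, strict)
# label the residue anomalous.

#' Scoring parameters
#'
#' @param outlier_threshold residue total above which (strictly) a residue
#'   is labeled an outlier; default 10.
#' @param flag_threshold per-feature score above which (strictly) the
#'   feature is flagged as highly unfavorable; default 2, i.e. density
#'   below 1 percent of the peak under base-10 logs.
#' @param npdf_floor densities strictly below this score `floor_score`
#'   instead of the logarithm; default 0.001.
#' @param floor_score fixed penalty for effectively-unobserved bins;
#'   default 5. Must be at least `-log(npdf_floor)` in the chosen base so
#'   the floor is a penalty, never a discount.
#' @param log_base base of the logarithm; default 10, under which a flag
#'   threshold of 2 corresponds to 1 percent of peak density.
#' @return object of class `hbos_params`.
#' @export
scoring_params <- function(outlier_threshold = 10, flag_threshold = 2,
                           npdf_floor = 0.001, floor_score = 5,
                           log_base = 10) {
  if (npdf_floor <= 0 || npdf_floor >= 1) stop("npdf_floor must be in (0, 1)")
  if (log_base <= 1) stop("log_base must exceed 1")
  if (floor_score < -log(npdf_floor, base = log_base)) {
    stop("floor_score must be at least -log(npdf_floor) so the floor is ",
         "a penalty, not a discount")
  }
  structure(list(outlier_threshold = outlier_threshold,
                 flag_threshold = flag_threshold,
                 npdf_floor = npdf_floor, floor_score = floor_score,
                 log_base = log_base),
            class = "hbos_params")
}

#' Per-feature HBOS component
#'
#' `log(1 / npdf)` in the configured base, or the fixed floor penalty when
#' the density is strictly below the floor (a density of exactly 0.001
#' scores `log10(1000) = 3` under the defaults, not 5).
#'
#' @param npdf_value density value(s) in `[0, 1]`.
#' @param params an `hbos_params`.
#' @return non-negative score(s); `NA` in gives `NA` out.
#' @export
hbos_component <- function(npdf_value, params = scoring_params()) {
  v <- as.numeric(npdf_value)
  bad <- !is.na(v) & (v < 0 | v > 1)
  if (any(bad)) stop("npdf values must lie in [0, 1]")
  out <- ifelse(v < params$npdf_floor, params$floor_score,
                log(1 / v, base = params$log_base))
  out[is.na(v)] <- NA_real_
  out
}

score_feature_columns <- function(features, db, params) {
  comp <- matrix(NA_real_, nrow(features), length(FEATURE_NAMES),
                 dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(nrow(features))) {
    for (f in FEATURE_NAMES) {
      v <- features[[f]][i]
      if (is.na(v)) next
      comp[i, f] <- hbos_component(
        lookup_npdf(db, features$type3[i], f, v), params)
    }
  }
  comp
}

#' Score one residue's feature vector
#'
#' Looks up the five npdf densities, applies the component rule and sums.
#' A residue with any missing feature is reported as not scored (the HBOS
#' total is a five-term sum; partial sums would not be comparable to the
#' threshold), never silently labeled safe or anomalous.
#'
#' @param fv a one-row data frame as produced by [extract_features()].
#' @param db an `hbos_db`.
#' @param params an `hbos_params`.
#' @return a one-row score data frame (see [score_chain()]).
#' @export
score_residue <- function(fv, db, params = scoring_params()) {
  stopifnot(is.data.frame(fv), nrow(fv) == 1)
  score_features(fv, db, params)
}

score_features <- function(features, db, params) {
  comp <- score_feature_columns(features, db, params)
  n_missing <- rowSums(is.na(comp))
  total <- ifelse(n_missing == 0, rowSums(comp), NA_real_)
  flagged <- comp > params$flag_threshold
  flagged[is.na(flagged)] <- FALSE
  out <- data.frame(
    chain_id = features$chain_id, resno = features$resno,
    icode = features$icode, type3 = features$type3,
    stringsAsFactors = FALSE
  )
  for (f in FEATURE_NAMES) {
    out[[paste0("score_", f)]] <- comp[, f]
  }
  out$total <- total
  out$scored <- n_missing == 0
  out$reason <- ifelse(out$scored, "ok", "missing_features")
  out$is_outlier <- !is.na(total) & total > params$outlier_threshold
  out$flagged_features <- apply(flagged, 1, function(z)
    paste(FEATURE_NAMES[z], collapse = ","))
  out
}

#' Score every residue of a chain
#'
#' Extracts features and scores each scoreable residue; GLY/ALA and
#' non-standard residues are included as unscored rows with a reason code
#' so the report covers the whole chain.
#'
#' @param chain an `hbos_chain`.
#' @param db an `hbos_db`.
#' @param params an `hbos_params`.
#' @param blocks block-definition table.
#' @return data frame of class `hbos_scores`: residue identity, the five
#'   per-feature scores (`score_phi`, ..., `score_d_block`), `total`,
#'   `scored`, `reason`, `is_outlier` and `flagged_features` (features
#'   whose score exceeds the flag threshold).
#' @examples
#' corp <- make_outlier_corpus(seed = 7, n_reference = 20, n_probe = 5)
#' db <- build_reference_from_structures(corp$reference)
#' score_chain(corp$probe[[1]]$chains[["A"]], db)
#' @export
score_chain <- function(chain, db, params = scoring_params(),
                        blocks = default_block_table()) {
  features <- extract_features(chain, blocks)
  scored <- if (nrow(features)) score_features(features, db, params) else NULL
  # carry non-scoreable residues through with a reason code
  rows <- list()
  for (r in chain$residues) {
    key <- paste(r$resno, r$icode)
    if (r$type3 %in% SCOREABLE_TYPES) {
      i <- which(paste(features$resno, features$icode) == key)
      rows[[length(rows) + 1L]] <- scored[i, , drop = FALSE]
    } else {
      empty <- data.frame(chain_id = chain$id, resno = r$resno,
                          icode = r$icode, type3 = r$type3,
                          stringsAsFactors = FALSE)
      for (f in FEATURE_NAMES) empty[[paste0("score_", f)]] <- NA_real_
      empty$total <- NA_real_
      empty$scored <- FALSE
      empty$reason <- "not_scoreable"
      empty$is_outlier <- FALSE
      empty$flagged_features <- ""
      rows[[length(rows) + 1L]] <- empty
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("hbos_scores", "data.frame")
  out
}

#' Probability distribution of residue HBOS totals
#'
#' Bins the totals of all scored residues (bin width 0.1 by default) into
#' a probability mass function over `[0, 5 * floor_score]`; used to
#' calibrate the outlier threshold against a trusted corpus, where the
#' mass above ~9.5 should be near zero.
#'
#' @param scores an `hbos_scores` data frame (or any data frame with a
#'   `total` column), or a numeric vector of totals.
#' @param bin_width histogram bin width (default 0.1).
#' @param upper domain maximum; defaults to 25 (five features times the
#'   default floor of 5).
#' @return data frame with columns `lower`, `upper`, `prob`; `prob` sums
#'   to 1.
#' @export
hbos_distribution <- function(scores, bin_width = 0.1, upper = 25) {
  totals <- if (is.numeric(scores)) scores else scores$total
  totals <- totals[!is.na(totals)]
  if (length(totals) == 0) stop("no scored residues to bin")
  b <- bin_spec(0, upper, bin_width)
  idx <- bin_index(pmin(totals, upper - bin_width / 2), b)
  counts <- tabulate(idx, nbins = b$count)
  data.frame(lower = b$lower + (seq_len(b$count) - 1) * b$width,
             upper = b$lower + seq_len(b$count) * b$width,
             prob = counts / sum(counts))
}
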