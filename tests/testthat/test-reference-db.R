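test_that("bin indexing uses half-open bins, wraps angles, caps distances", {
  ab <- bin_spec(0, 360, 5)
  expect_equal(bin_index(62.5, ab, wrap = TRUE), 13L)  # floor(62.5/5) zero-based 12
  expect_equal(bin_index(0.0, ab, wrap = TRUE), 1L)
  expect_equal(bin_index(5.0, ab, wrap = TRUE), 2L)    # lower edge belongs up
  expect_equal(bin_index(360, ab, wrap = TRUE), 1L)    # wraps to first bin
  expect_equal(bin_index(359.999, ab, wrap = TRUE), 72L)
  db <- bin_spec(0, 10, 0.05)
  expect_true(is.na(bin_index(11.9, db)))
  expect_equal(bin_index(3.27, db), 66L)
  expect_error(bin_spec(0, 360, 7), "tile")
})

test_that("peak normalization divides by the maximum and keeps zeros", {
  expect_equal(normalize_to_peak(c(2, 10, 5)), c(0.2, 1.0, 0.5))
  expect_equal(normalize_to_peak(7), 1.0)
  expect_equal(normalize_to_peak(c(0, 0, 0)), c(0, 0, 0))
  expect_error(normalize_to_peak(c(-1, 2)), "negative")
  # scale invariance
  set.seed(3)
  k <- stats::rpois(72, 4)
  expect_equal(normalize_to_peak(k), normalize_to_peak(17 * k))
})

test_that("reference build places all mass where the corpus was built", {
  # corpus of GLN peptides all at phi = 300 -> density 1 in the 300-305 bin
  peps <- lapply(1:3, function(i)
    build_peptide(peptide_spec("AQQQA", phi = 300, psi = 320, chi1 = 300)))
  db <- build_reference_from_structures(peps, dedup_threshold = NA)
  tab <- db$tables[["GLN.phi"]]
  expect_equal(tab$density[61], 1)           # 300 / 5 = 60 zero-based
  expect_equal(sum(tab$density > 0), 1)
  expect_equal(tab$sample_count, 9L)

  # duplicating the corpus leaves every density unchanged
  db2 <- build_reference_from_structures(c(peps, peps), dedup_threshold = NA)
  for (key in names(db$tables)) {
    expect_equal(db2$tables[[key]]$density, db$tables[[key]]$density)
  }

  # a corpus with no scoreable residues is an explicit error
  gly <- list(build_peptide(peptide_spec("GGG")))
  expect_error(build_reference_from_structures(gly), "empty corpus")
})

test_that("tied modes both normalize to density 1", {
  counts <- numeric(72); counts[10] <- 6; counts[40] <- 6; counts[20] <- 3
  d <- normalize_to_peak(counts)
  expect_equal(d[10], 1); expect_equal(d[40], 1); expect_equal(d[20], 0.5)
})

test_that("accumulated histograms match a brute-force loop", {
  n <- 800
  vals <- sample_features(feature_sample_spec(
    "GLN", "chi1", modes = c(62.5, 292.5), sds = 15, weights = c(0.5, 0.5),
    n = n, seed = 21))
  feats <- do.call(rbind, lapply(vals, function(v)
    feature_row("GLN", chi1 = v, phi = NA, psi = NA,
                d_sidechain = NA, d_block = NA)))
  hset <- hbosval:::new_histogram_set()
  hbosval:::accumulate(feats, hset)
  got <- hset$counts[["GLN.chi1"]]
  brute <- numeric(72)
  for (v in vals) {
    k <- floor((v %% 360) / 5) + 1
    brute[k] <- brute[k] + 1
  }
  expect_equal(got, brute)
  expect_equal(sum(got), n)
  # missing values contribute nothing
  expect_equal(sum(hset$counts[["GLN.phi"]]), 0)
})

test_that("lookup reads the bin containing the value, zero when unobserved", {
  peps <- lapply(1:2, function(i)
    build_peptide(peptide_spec("AQQQA", phi = 302.5, psi = 320, chi1 = 300)))
  db <- build_reference_from_structures(peps)
  expect_equal(lookup_npdf(db, "GLN", "phi", 302.5), 1)   # peak bin
  expect_equal(lookup_npdf(db, "GLN", "phi", 300.0), 1)   # same bin's lower edge
  expect_equal(lookup_npdf(db, "GLN", "phi", 100.0), 0)   # empty bin
  expect_equal(lookup_npdf(db, "GLN", "d_block", 99), 0)  # beyond the cap
  expect_error(lookup_npdf(db, "GLN", "chi9", 10), "no npdf table")
})

test_that("database serialization round-trips bit-exactly and validates", {
  db <- small_corpus_db()
  f <- tempfile(fileext = ".json")
  save_db(db, f)
  db2 <- load_db(f)
  expect_equal(length(db2$tables), 90)
  for (key in names(db$tables)) {
    expect_identical(db2$tables[[key]]$density, db$tables[[key]]$density)
    expect_identical(db2$tables[[key]]$sample_count,
                     db$tables[[key]]$sample_count)
  }
  expect_equal(db2$metadata$corpus, db$metadata$corpus)

  # truncation is a parse error, not silent corruption
  txt <- readLines(f)
  f2 <- tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 500), f2)
  expect_error(load_db(f2), "cannot read")

  # missing tables are named at load time
  raw <- jsonlite::read_json(f, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  raw$tables <- raw$tables[-(1:5)]
  f3 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, f3, auto_unbox = TRUE, digits = NA)
  expect_error(load_db(f3), "missing tables")

  # schema version mismatch is explicit
  raw2 <- jsonlite::read_json(f, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  raw2$version <- "99.0"
  f4 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw2, f4, auto_unbox = TRUE, digits = NA)
  expect_error(load_db(f4), "version mismatch")
})

test_that("a dominant sampled mode lands within one bin of the truth", {
  vals <- sample_features(feature_sample_spec(
    "GLU", "chi1", modes = c(185, 62.5), sds = c(12, 12),
    weights = c(0.8, 0.2), n = 10000, seed = 8))
  feats <- do.call(rbind, lapply(vals, function(v)
    feature_row("GLU", chi1 = v, phi = NA, psi = NA,
                d_sidechain = NA, d_block = NA)))
  hset <- hbosval:::new_histogram_set()
  hbosval:::accumulate(feats, hset)
  dens <- normalize_to_peak(hset$counts[["GLU.chi1"]])
  peak_bin <- which(dens == 1)
  true_bin <- floor(185 / 5) + 1
  expect_lte(min(abs(peak_bin - true_bin)), 1)
})

test_that("file-based reference build parses, deduplicates and warns", {
  dir <- tempfile(); dir.create(dir)
  # two files; one has two identical chains (the duplicate must not double counts)
  s1 <- build_peptide(peptide_spec("AQWEQA", phi = 300, psi = 320))
  chB <- s1$chains[["A"]]; chB$id <- "B"
  s1dup <- hbosval:::new_structure("dup", list(s1$chains[["A"]], chB))
  write_pdb(s1dup, file.path(dir, "a.pdb"))
  write_pdb(build_peptide(peptide_spec("AKRNDA", phi = 300, psi = 320)),
            file.path(dir, "b.pdb"))
  writeLines("not a pdb at all", file.path(dir, "broken.pdb"))

  expect_warning(
    db <- build_reference(list.files(dir, full.names = TRUE),
                          corpus_label = "tiny"),
    "skipping")
  expect_equal(db$metadata$n_files, 2L)
  # deduplication halved the duplicated chain: GLN appears in one chain of
  # s1 (2 copies of Q per chain) plus one in b -> without dedup it would be 4
  expect_equal(db$tables[["GLN.chi1"]]$sample_count, 2L)
})
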