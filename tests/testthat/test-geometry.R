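test_that("dihedral_deg matches known configurations and an external oracle", {
  expect_equal(dihedral_deg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral_deg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)),
               180)
  expect_equal(dihedral_deg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)),
               270)
  # cross-check the sign convention against bio3d on random quadruples
  set.seed(11)
  for (k in 1:25) {
    p <- matrix(stats::rnorm(12), 4, 3)
    ours <- dihedral_deg(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)  # (-180, 180]
    expect_equal(ours %% 360, as.numeric(ref) %% 360, tolerance = 1e-6)
  }
})

test_that("dihedral output stays in [0,360), is reversal-invariant, mirrors negate", {
  set.seed(5)
  for (k in 1:50) {
    p <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    d1 <- dihedral_deg(p[1, ], p[2, ], p[3, ], p[4, ])
    d2 <- dihedral_deg(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_gte(d1, 0); expect_lt(d1, 360)
    # an IUPAC torsion reads the same from either end of the atom chain
    expect_equal(d1, d2, tolerance = 1e-8)
    # a mirror image (improper rigid transform) negates it
    m <- p; m[, 3] <- -m[, 3]
    d3 <- dihedral_deg(m[1, ], m[2, ], m[3, ], m[4, ])
    expect_equal((d1 + d3) %% 360, 0, tolerance = 1e-8)
  }
  expect_error(
    dihedral_deg(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "collinear")
})

test_that("phi/psi/chi1 honor termini, chain breaks and missing atoms", {
  s <- build_peptide(peptide_spec("LELLL", phi = 250, psi = 140, chi1 = 290))
  res <- s$chains[["A"]]$residues
  expect_true(is.na(compute_phi(NULL, res[[1]])))
  expect_true(is.na(compute_psi(res[[5]], NULL)))
  expect_equal(compute_phi(res[[1]], res[[2]]), 250, tolerance = 1e-6)
  expect_equal(compute_psi(res[[2]], res[[3]]), 140, tolerance = 1e-6)
  expect_equal(compute_chi1(res[[2]]), 290, tolerance = 1e-6)

  # author-numbering gap breaks the torsion even with close atoms
  gap <- res
  gap[[3]]$resno <- 10L
  expect_true(is.na(compute_phi(gap[[2]], gap[[3]])))

  # spatial chain break: shift the rest of the chain away
  far <- res[[3]]
  far$atoms[, c("x", "y", "z")] <- far$atoms[, c("x", "y", "z")] + 50
  expect_true(is.na(compute_phi(res[[2]], far)))

  # missing backbone N
  noN <- res[[2]]
  noN$atoms <- noN$atoms[noN$atoms$name != "N", ]
  expect_true(is.na(compute_phi(res[[1]], noN)))

  # GLY has no chi1; LEU without CG has none either
  g <- build_peptide(peptide_spec("AGA"))$chains[["A"]]$residues[[2]]
  expect_true(is.na(compute_chi1(g)))
  noCG <- res[[2]]
  noCG$atoms <- noCG$atoms[noCG$atoms$name != "CG", ]
  expect_true(is.na(compute_chi1(noCG)))
})

test_that("mass centroid is the standard mass-weighted mean", {
  one <- data.frame(name = "CB", element = "C", x = 1, y = 2, z = 3)
  expect_equal(mass_centroid(one), c(1, 2, 3))
  two <- data.frame(name = c("C1", "C2"), element = "C",
                    x = c(0, 2), y = 0, z = 0)
  expect_equal(mass_centroid(two), c(1, 0, 0))
  co <- data.frame(name = c("C", "O"), element = c("C", "O"),
                   x = c(0, 1), y = 0, z = 0)
  expect_equal(mass_centroid(co)[1], 15.999 / (12.011 + 15.999),
               tolerance = 1e-6)
  expect_error(mass_centroid(co[0, ]), "at least one atom")
  expect_error(mass_centroid(data.frame(name = "Q", element = "QQ",
                                        x = 0, y = 0, z = 0)),
               "atomic mass")
})

test_that("side-chain size and block length follow their definitions", {
  # ALA: side chain is CB only, so d_sidechain = |CA - CB|
  ala <- build_peptide(peptide_spec("GAG"))$chains[["A"]]$residues[[2]]
  d <- compute_d_sidechain(ala)
  expect_equal(d, sqrt(sum((atom_xyz(ala, "CA") - atom_xyz(ala, "CB"))^2)),
               tolerance = 1e-12)

  # LEU: hand-computed centroid arithmetic on explicit coordinates
  leu <- hbosval:::new_residue("LEU", 1L, "", data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C"),
    x = c(-1.2, 0, 1.0, 1.5, 0.5, 2.5, 3.2, 3.2),
    y = c(0.5, 0, 1.0, 2.0, -1.4, 0, 1, -1),
    z = 0, stringsAsFactors = FALSE))
  cen_block <- c(mean(c(2.5, 3.2, 3.2)), mean(c(0, 1, -1)), 0)
  expect_equal(compute_d_block(leu), sqrt(sum(cen_block^2)),
               tolerance = 1e-12)
  sc <- leu$atoms[leu$atoms$name %in% c("CB", "CG", "CD1", "CD2"), ]
  cen_sc <- colSums(sc[, c("x", "y", "z")] * 12.011) / (4 * 12.011)
  expect_equal(compute_d_sidechain(leu), sqrt(sum(cen_sc^2)),
               tolerance = 1e-12)

  # incomplete side chain -> missing, never a truncated value
  part <- leu
  part$atoms <- part$atoms[part$atoms$name != "CD2", ]
  expect_true(is.na(compute_d_sidechain(part)))
  expect_true(is.na(compute_d_block(part)))
  none <- leu
  none$atoms <- none$atoms[none$atoms$name %in% c("N", "CA", "C", "O"), ]
  expect_true(is.na(compute_d_sidechain(none)))

  # equal-mass centroid arithmetic: (2.9667, 0, 0) from CA at the origin
  expect_equal(compute_d_block(leu), 2.9667, tolerance = 1e-4)
})

test_that("extract_features covers scoreable residues only, in order", {
  ch <- build_peptide(peptide_spec("ACDEF"))$chains[["A"]]
  fv <- extract_features(ch)
  expect_equal(nrow(fv), 4)  # ALA excluded
  expect_equal(fv$type3, c("CYS", "ASP", "GLU", "PHE"))
  expect_true(is.na(fv$psi[4]))  # C-terminal residue

  glyonly <- build_peptide(peptide_spec("GGGG"))$chains[["A"]]
  expect_equal(nrow(extract_features(glyonly)), 0)
})

test_that("builder targets are recovered and features are rigid-motion invariant", {
  spec <- peptide_spec("ALELA", phi = c(NA, 252.3, 300, 310, NA),
                       psi = c(NA, 134.5, 320, 100, NA),
                       chi1 = c(NA, 286.0, 300, 180, NA))
  s <- build_peptide(spec)
  fv <- extract_features(s$chains[["A"]])
  expect_equal(fv$phi[fv$resno == 2], 252.3, tolerance = 1e-4)
  expect_equal(fv$psi[fv$resno == 2], 134.5, tolerance = 1e-4)
  expect_equal(fv$chi1[fv$resno == 2], 286.0, tolerance = 1e-4)

  moved <- rigid_transform(s, seed = 99)
  fv2 <- extract_features(moved$chains[["A"]])
  for (col in c("phi", "psi", "chi1", "d_sidechain", "d_block")) {
    expect_equal(fv[[col]], fv2[[col]], tolerance = 1e-6)
  }
})

test_that("d_block is bounded by the farthest distal atom and d_sidechain positive", {
  corp <- small_corpus()
  for (s in corp$reference[1:5]) {
    for (r in s$chains[["A"]]$residues) {
      db_val <- compute_d_block(r)
      if (is.na(db_val)) next
      blocks <- default_block_table()
      atoms <- hbosval:::block_entry(blocks, r$type3)$distal_atoms
      ca <- atom_xyz(r, "CA")
      dmax <- max(vapply(atoms, function(a)
        sqrt(sum((atom_xyz(r, a) - ca)^2)), 0))
      expect_lte(db_val, dmax + 1e-9)
      ds <- compute_d_sidechain(r)
      if (!is.na(ds)) expect_gt(ds, 0)
    }
  }
})
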