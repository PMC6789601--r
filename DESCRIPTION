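Package: hbosval
Title: Histogram-Based Outlier Scoring for Protein Model Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised validation of protein coordinate models using a
    histogram-based outlier score (HBOS) over five per-residue geometric
    features: the backbone torsions phi and psi, the first side-chain
    torsion chi1, the distance from CA to the side-chain mass centroid,
    and the distance from CA to the mass centroid of the side chain's
    distal block. Peak-normalized histogram densities are built from a
    reference corpus of trusted structures, serialized as a JSON
    database, and used to score and flag anomalous residues in target
    models such as those built from cryo-EM density maps. Includes a
    geometry-controlled synthetic peptide builder so the full pipeline
    can be exercised and calibrated without external structure
    downloads, plus TSV/JSON report writers and a Chimera attribute
    exporter for visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
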