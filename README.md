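# hbosval

Unsupervised validation of protein coordinate models with a
histogram-based outlier score (HBOS).

Atomic models built into cryo-EM density maps can carry conformational
errors that slip past deposition-time geometry checks: torsion angles sit
in favorable regions while the side chain as a whole has been bent into a
shape essentially never seen in high-resolution crystal structures.
`hbosval` targets exactly that failure mode. It describes every residue by
five geometric features —

- **φ, ψ** — backbone torsions C(i−1)–N–CA–C and N–CA–C–N(i+1),
- **χ₁** — the first side-chain torsion N–CA–CB–γ,
- **d_sidechain** — distance from CA to the mass centroid of all heavy
  side-chain atoms ("side-chain size"),
- **d_block** — distance from CA to the mass centroid of the side chain's
  distal block, its terminal rigid group such as the glutamate carboxylate
  or the leucine isopropyl ("block length"),

all angles on a 0–360° scale. From a trusted reference corpus it builds,
for each of the 18 residue types with a χ₁ (all but GLY/ALA), a binned
density per feature (5° bins for angles, 0.05 Å for distances), normalized
so the highest peak equals 1 — an *npdf*. A residue in a target model then
scores

```
HBOS = Σᵢ log₁₀( 1 / npdfᵢ(vᵢ) ),   i over the five features,
```

with any bin whose density falls below 0.001 contributing a fixed floor
score of 5 instead of an unbounded logarithm. Residues with HBOS strictly
greater than 10 are labeled outliers; individual components above 2 mark
the offending feature. Because the score multiplies (in log space) the
rarity of all five features, it flags residues whose *combination* of
features is implausible even when each one alone looks acceptable — the
blind spot of single-feature validation pipelines.

The package is a complement to, not a replacement for, deposition-time
validators: it knows nothing about clashes, bond lengths or map fit.

## What's in the box

| Layer | Functions |
| --- | --- |
| Structure I/O | `parse_structure()`, `sequence_identity()`, `deduplicate_chains()` |
| Features | `extract_features()`, `compute_phi()/psi()/chi1()`, `compute_d_sidechain()/d_block()`, `dihedral_deg()`, `mass_centroid()` |
| Reference DB | `build_reference()`, `build_reference_from_structures()`, `save_db()`/`load_db()`, `lookup_npdf()`, `bin_index()`, `normalize_to_peak()` |
| Scoring | `scoring_params()`, `hbos_component()`, `score_residue()`, `score_chain()`, `hbos_distribution()` |
| Synthetic fixtures | `peptide_spec()`/`build_peptide()`, `write_pdb()`, `sample_features()`, `make_outlier_corpus()` |
| Reports / CLI | `score_report()`, `write_report_tsv()/json()`, `write_chimera_attributes()`, `cmd_build_ref()`, `cmd_score()`, `inst/scripts/hbos.R` |

Chain deduplication removes non-crystallographic-symmetry copies: chains
with ≥ 95% global-alignment identity to an already-kept chain of the same
entry are ignored when building the reference.

## Worked example

The built-in generator creates a labeled corpus: reference peptides drawn
from one tight torsion basin, plus probe peptides in which a few residues
are planted at conformations the reference has never seen.

```r
library(hbosval)

corp <- make_outlier_corpus(seed = 1, n_reference = 200,
                            n_probe = 100, n_planted = 20)
db <- build_reference_from_structures(corp$reference,
                                      corpus_label = "synthetic helix corpus")
db
#> <hbos_db> 90 npdf tables, 1400 reference residues
#>   corpus: synthetic helix corpus

i  <- corp$truth$peptide[1]          # a probe with one planted residue
sc <- score_chain(corp$probe[[i]]$chains[["A"]], db)
score_report(sc, mode = "full")
#>   Residue Index Chain B-Dist S-Dist   Phi    Psi Chi_1  Total Outlier      Flagged
#> 1     TYR     2     A      0      0 0.146 0.1249 0.000  0.271   FALSE
#> 2     ARG     3     A      0      0 5.000 5.0000 5.000 15.000    TRUE phi,psi,chi1
#> 3     ARG     4     A      0      0 0.301 0.0512 0.136  0.488   FALSE
#> 4     LEU     5     A      0      0 0.319 0.8016 0.130  1.251   FALSE
#> 5     CYS     6     A      0      0 0.000 0.1120 0.317  0.429   FALSE
#> 6     THR     7     A      0      0 0.000 0.5643 0.362  0.926   FALSE
```

The planted residue (ARG 3) lands in zero-density bins for all three
torsions, so each contributes the floor score of 5; its total of 15
exceeds the threshold of 10 and it is the only labeled outlier. `B-Dist`
and `S-Dist` are the block-length and side-chain-size components; values
above 2 would be listed in `Flagged`, mirroring the red highlight of
interactive validation reports. Terminal residues (1 and 8) lack φ or ψ
and are reported as unscored rather than silently passed.

From a shell, the same pipeline over files:

```sh
Rscript inst/scripts/hbos.R build-ref --in ref_pdbs/ --out db.json
Rscript inst/scripts/hbos.R score --in model.pdb --db db.json \
        --chain A --threshold 10 --format tsv --out report \
        --chimera-attr model.attr
```

`model.attr` is a Chimera attribute-assignment file mapping every scored
residue to its HBOS total, for coloring structures by score in any viewer
that reads the format.

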