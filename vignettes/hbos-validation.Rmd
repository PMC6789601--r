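---
title: "Histogram-based outlier scoring of protein residue conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-based outlier scoring of protein residue conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbosval)
```

## The problem and the model

Models built into medium-resolution cryo-EM maps inherit conformations
from modeling software under weak experimental restraint. A residue can
satisfy every single-feature check — torsions in favorable Ramachandran
and rotamer regions, bonds and angles near ideal — while its side chain
as a whole has been displaced into a geometry that essentially never
occurs in high-resolution crystal structures. Checks that look at one
feature at a time cannot see this, because the anomaly lives in the
*combination* of features.

`hbosval` scores each residue by how rare its five-feature conformation
is relative to a trusted reference corpus. The features are the backbone
torsions $\varphi$ and $\psi$, the first side-chain torsion $\chi_1$, the
distance $d_{sidechain}$ from CA to the mass centroid of all heavy
side-chain atoms, and the distance $d_{block}$ from CA to the mass
centroid of the side chain's *distal block* — its terminal rigid group
(carboxylate of GLU, isopropyl of LEU, aromatic ring of PHE, and so on).
The two distances are the load-bearing additions: rigid-geometry checks
do not constrain how far the tail of a side chain sits from the backbone,
and $d_{block}$ in particular is sensitive to exactly the tail
displacements that slip through.

For each of the 18 residue types with a $\chi_1$ (GLY and ALA have none
and are not scored), each feature's reference values are binned — 5° bins
over $[0°, 360°)$ for angles, 0.05 Å bins over $[0, 10]$ Å for distances
— and the histogram is rescaled by its highest peak, giving a
peak-normalized density ("npdf") with maximum exactly 1. That makes 90
tables in a reference database. A residue with feature values $v_i$ then
scores

$$\mathrm{HBOS} = \sum_{i=1}^{5} \log_{10}\!\frac{1}{\mathrm{npdf}_i(v_i)},$$

so a value in the peak bin contributes 0 and rarer values contribute
more. Bins with density strictly below 0.001 contribute a fixed floor of
5 instead of the (possibly infinite) logarithm. A residue is labeled an
outlier when its total is strictly greater than 10; an individual
component strictly above 2 (density below 1% of peak) marks that feature
as highly unfavorable in reports. The model is a histogram flavor of
naive Bayes: features are treated independently, which deliberately
over-counts correlated rarity — acceptable for a screening score whose
labels are meant to be inspected, not trusted blindly.

## Parameters that matter

| Parameter | Default | Meaning |
| --- | --- | --- |
| angle bin width | 5° | resolution of torsion npdfs |
| distance bin width | 0.05 Å | resolution of distance npdfs |
| distance cap | 10 Å | histogram domain; beyond it density is 0 |
| `npdf_floor` | 0.001 | density below which the floor applies (strict `<`) |
| `floor_score` | 5 | component value in effectively-unobserved bins |
| `log_base` | 10 | base of the component logarithm |
| `flag_threshold` | 2 | per-feature "highly unfavorable" mark (strict `>`) |
| `outlier_threshold` | 10 | residue label cutoff (strict `>`) |
| dedup threshold | 0.95 | identity at which NCS chain copies are dropped |

The logarithm base is not dictated by the scoring equation itself; we use
base 10 because it makes the printed thresholds cohere: a flag at 2 is
exactly "density below 1% of peak", a density at the floor boundary
scores $\log_{10} 1000 = 3$, and the floor of 5 then sits strictly above
it, acting as a discontinuous extra penalty for bins that are effectively
unobserved rather than merely rare. The base is a parameter of
`scoring_params()` for anyone who wants nats or bits, and the constructor
refuses configurations where the floor would *discount* rather than
penalize. The floor comparison is strict (`< 0.001`), so a density of
exactly 0.001 scores 3, not 5. Both labeling comparisons are strict as
well: a total of exactly 10 is not an outlier.

Residues missing any feature — chain termini (no $\varphi$ or $\psi$),
residues adjacent to chain breaks, or residues with missing atoms — are
reported as *unscored* with a reason code. The five-term sum is only
comparable to the threshold when all five terms exist; scoring a subset
would silently shrink totals toward "safe".

## Numerical and degenerate-input choices

- **Torsion convention.** `dihedral_deg()` computes the signed IUPAC
  torsion by the atan2 construction and maps $(-180°, 180°]$ to
  $[0°, 360°)$ by adding 360 to negatives; exactly 360 wraps to 0.
  Collinear atom triples raise an explicit degenerate-geometry error.
- **Bins are half-open** $[e, e + w)$; an angle equal to 360 wraps to the
  first bin; distances at or beyond the cap are out of range and read as
  density 0, which the floor then converts to the maximal component — cap
  overflow is treated as "unobserved", not as an error.
- **Chain breaks.** $\varphi$/$\psi$ are computed only across genuine
  peptide bonds: consecutive author numbering and a C–N distance of at
  most 2.0 Å. This prevents nonsense torsions across gaps in partially
  modeled chains.
- **Alternate locations.** The highest-occupancy conformer wins, ties to
  the first in file — the common validation-tool convention.
- **Nonstandard residues** (MSE and friends) are skipped and reported,
  never silently remapped to a parent type.
- **Mass centroids** use conventional atomic masses over heavy atoms
  only; deposited models typically lack hydrogens, and adding their 1 u
  when present would shift centroids inconsistently between models.
- **Incomplete side chains** yield a missing $d_{sidechain}$ rather than
  a centroid over whatever atoms happen to be present, which would
  otherwise produce deceptively short values for truncated side chains.
- **No smoothing or pseudocounts** in the npdfs: raw counts are divided
  by the peak. Sparsity is handled entirely by the scoring floor, keeping
  the density estimate faithful to what the corpus actually contains.

Two genuinely open design points deserve a note. First, the distal-block
atom memberships are shipped as a plain-text table
(`inst/extdata/block_definitions.tsv`), defaulting to the terminal
chemical group of each side chain; block decompositions vary slightly
between authors, and making the table data rather than code means a
different decomposition is a one-file change with no retesting of logic.
Second, "95% sequence similarity" for NCS removal is implemented as
global-alignment identity over alignment length (match 1, mismatch 0,
simple gap penalty), the conventional reading; the threshold and the
choice of denominator are both configurable.

## The synthetic corpus: what it shows and what it cannot

Real reference corpora are thousands of crystal structures; building one
is a download-and-curation exercise, not a method question. For
development, calibration and testing the package ships a generator of
geometry-controlled peptides.

`build_peptide()` grows a chain by sequential internal-coordinate
extension (the NeRF construction): each atom is placed from a bond
length, a plane angle and a torsion relative to three already-placed
atoms. Backbone $\varphi/\psi/\omega$ and $\chi_1$ therefore equal their
targets to floating-point accuracy — the builder/extractor round trip is
the package's core geometric oracle, and it closes to below $10^{-10}$
degrees. Bond lengths and angles come from standard amino-acid geometry
tables; side-chain torsions beyond $\chi_1$ are fixed at idealized
rotamer/planar values; L-chirality is enforced through the C–N–CA–CB
improper torsion (−122.8°) measured from real structures. Aromatic rings
are built by internal coordinates too, so ring closure is approximate at
the 0.01 Å level — irrelevant for features measured from CA but worth
knowing before using the builder for anything energy-related.

`make_outlier_corpus()` draws reference peptides from a single tight
torsion basin ($\varphi \sim 297°$, $\psi \sim 318°$, $\chi_1 \sim 300°$,
each with an 8° spread — helix-like backbone, minus rotamer) and plants
probe residues at the antipodal torsions (+180° on each), which the
reference cannot reach at 8° spread: those bins have exactly zero
density, so each planted torsion contributes the floor of 5 and every
planted residue totals at least 15. The corpus sizes used throughout the
tests and the acceptance script — 200 reference peptides (≈ 1400
scoreable residues) and 100 probes with 20 plants — keep the full
pipeline under half a minute while leaving every one of the 90 tables
populated (the first reference peptides cycle deterministically through
all 18 types).

What passing on this corpus demonstrates: the plumbing end to end —
building, writing and parsing coordinates, feature extraction,
accumulation, normalization, serialization, scoring, thresholding and
reporting — plus the floor guarantee and calibration self-consistency
(self-scoring the reference leaves essentially no mass above 9.5, and
false labels on clean probes stay far under 1%). What it cannot
demonstrate: performance on real cryo-EM models. Real reference
distributions are multimodal with correlated features, real anomalies
are subtler than antipodal torsions, and real $d_{block}$ outliers arise
from coordinate-level distortion at fixed torsions — a regime ideal
geometry cannot produce at all. Validating against deposited entries
requires the real reference corpus and is out of scope here.

```{r corpus, eval = FALSE}
corp <- make_outlier_corpus(seed = 1, n_reference = 200,
                            n_probe = 100, n_planted = 20)
db <- build_reference_from_structures(corp$reference)
sc <- score_chain(corp$probe[[corp$truth$peptide[1]]]$chains[["A"]], db)
score_report(sc, mode = "outliers")
```

## Known limitations

- Features are scored independently; correlated rarity is over-penalized
  and compensating correlations are invisible — the usual naive-Bayes
  bias, accepted here for the sake of an unsupervised, training-free
  score.
- No environment terms: neighbors, contacts, map fit and clashes are all
  outside the five features.
- The score is only as good as its reference database. A database built
  from a narrow corpus (like the synthetic one) labels everything outside
  that corpus; a production database needs a broad high-resolution set
  with NCS removed.
- Distances beyond the 10 Å cap score the floor; for the 20 standard
  amino acids the cap is generous (the longest side chains centroid well
  under 8 Å), but exotic residues would need a wider domain.
- Residues with missing features are excluded from labeling, so heavily
  incomplete models yield short reports — check the unscored reasons, not
  just the outlier list.
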