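---
title: "Methods: clustered fingerprint classifiers for non-peptidic epitopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustered fingerprint classifiers for non-peptidic epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npek)
```

## The problem

Most epitope-prediction tools target peptides, yet lipids, glycolipids,
oligosaccharides, nucleobase derivatives and small haptens are also
recognized by B-cell and T-cell receptors. `npek` treats this as a
two-step molecular classification problem over a large, heterogeneous
small-molecule background:

1. **Cluster** the molecule collection into homogeneous structural classes,
   because lipids, carbohydrates and small aromatics plausibly engage the
   immune system through different mechanisms and, statistically, because a
   single global classifier would mostly learn the class boundary itself.
2. **Classify** within each structural class, per assay (B-cell and
   T-cell), with a probabilistic model over substructure-count features,
   and explain the decision through enrichment statistics of individual
   substructures.

## Encodings: why counts, and why two different fingerprints

Both steps use circular (Morgan/ECFP-type) fingerprints: every atom's
bonded neighborhood up to a radius is condensed into a 32-bit integer
identifier by iterative neighborhood hashing. Atom invariants are (atomic
number, heavy-atom degree, hydrogen count, formal charge, ring membership,
aromaticity), plus the tetrahedral parity tag for stereocenters when the
chiral option is on; achiral molecules therefore encode identically under
both settings. Identifier collisions are accepted, as is standard for
unfolded fingerprints.

The two steps deliberately use different variants:

* **Clustering** uses *folded bit* fingerprints (1024 bits, radius 3,
  non-chiral): a fixed-length, presence/absence geometry suitable for
  k-means in Euclidean space.
* **Classification** uses *unfolded count* fingerprints (radius 3,
  chiral). Counts matter because immunologically meaningful motifs are
  often repetitive: a glycolipid with a C26 acyl chain and its C10 analog
  contain the same set of substructures and are indistinguishable to a bit
  fingerprint, but their interior-CH2 environment counts differ strongly.
  The package's synthetic "bit-blind" scenario (`bit_blind_spec()`)
  isolates exactly this situation and is part of the test suite.

Molecules enter through OpenBabel canonicalization; the canonical SMILES
is parsed into a molecular graph by the package's own parser. Implicit
hydrogens follow the standard organic-subset valence rules; directional
bond symbols are read as single bonds because cis/trans geometry does not
enter the environment invariants. The chirality tag is the `@`/`@@`
parity as written in the canonical SMILES (stable because OpenBabel fixes
neighbor order), not a CIP assignment; this is sufficient to distinguish
enantiomers and diastereomers under a fixed canonicalization scheme.

## Feature-matrix construction

Per cluster, count fingerprints are assembled into a molecules-by-features
table and filtered:

* **Identical-fingerprint removal** — molecules with exactly equal count
  vectors collapse to one row; on conflicting labels the survivor is
  positive (a known epitope should never be silently converted to a
  negative), and the conflict is logged.
* **Trimming** (`min_occurrence`, default 10) — a feature must occur in at
  least 10 molecules of the cluster; rarer features are unlearnable at
  these sample sizes and inflate the multiple-testing burden.
* **Correlation pruning** (`pcc_threshold`, default 0.8) — circular
  fingerprints are intrinsically nested (a radius-2 environment implies
  its radius-1 core), so feature counts can correlate almost perfectly. A
  greedy scan keeps a feature only if its absolute Pearson correlation
  with every already-kept feature is at most 0.8. Greedy pruning is
  order-dependent and no canonical order exists; the default scan order is
  ascending feature identifier, which is arbitrary but deterministic, and
  an optional ranking argument lets callers scan in e.g. chi-squared
  order instead. Zero-variance columns have undefined correlation; they
  are kept (treated as correlation 0) with a message rather than silently
  dropped.

## Clustering

k-means (Lloyd iterations, best of `n_init = 10` seeded random starts by
inertia) over the folded bit matrix. Assignment ties break toward the
lowest centroid index; a centroid left empty is re-seeded at the sample
farthest from its current centroid (with bounded retries, since duplicated
rows can make centroids unfillable). Inertia — the sum of squared
sample-to-centroid distances — is exported as a curve over k
(`inertia_curve()`) for elbow-style judgment; the curve for realistic
molecular data flattens gradually, so the package deliberately performs
**no automatic k selection**. The default k = 8 follows the regime where
the inertia gain per extra cluster becomes marginal on the data this
method was developed for; users should inspect the curve on their own
collections. A 2-component PCA projection is provided for visualization
only; it plays no role in model fitting.

## Classifiers and the evaluation protocol

Per cluster and assay, the package trains models with deliberately
*default* hyperparameters — tuning on these small positive sets would
overfit:

* **Random forest** (the production model): 100 trees, unlimited depth,
  sqrt(p) candidate features per split; the score is the fraction of trees
  voting positive.
* **k-NN** (k = 5) and a **single-hidden-layer neural network** (100
  units, at most 200 epochs) as comparison models.
* **Similarity baseline**: a molecule's score is its maximum
  count-Tanimoto similarity, `sum(min)/sum(max)` over feature counts, to
  the known epitopes of the cluster. This baseline represents pure
  structural memorization; a learned model is only interesting where it
  matches or beats it.
* **Shuffled-label null** (`dummy_rf`): the random forest trained on a
  label vector permuted uniformly at random (positive count preserved
  exactly), shuffled once per CV repeat *before* splitting. Its ROC-AUC
  should be indistinguishable from 0.5; anything else indicates leakage
  or a stratification artifact in the harness itself.

Evaluation is 3-times-repeated 5-fold stratified cross-validation with
ROC-AUC (Mann–Whitney formulation, ties counting one half). Per-fold
positive counts differ by at most one. The reported value is the
arithmetic mean of the 15 fold AUCs with its standard deviation. Three
leakage guards are built in and tested:

* similarity scoring of a held-out fold uses only training-fold positives,
  so a molecule is never its own reference;
* optional top-k chi-squared feature selection is re-fit inside each
  training fold (a whole-data ranking variant exists behind a flag for
  emulation purposes, and is not the default);
* the dummy model's shuffle and the fold splitter use distinct derived
  seeds, so their random streams cannot couple.

All randomness descends from explicit integer seeds: a run seed
deterministically derives per-repeat seeds for the splitter, the shuffler
and the models, so any reported number can be replayed exactly.

## Substructure enrichment statistics

For interpretation, every retained feature is tested for association of
its class-wise *count sums* with epitope status: observed = the feature's
total count within each class; expected = the feature's overall total
split by class share of molecules; the statistic is the usual sum of
squared Pearson residuals with one degree of freedom (two classes).
p-values are Bonferroni-corrected with m = the number of features
surviving trimming and pruning in that cluster, separately per assay.
Three complementary statistics accompany the p-value:

* **epitope coverage** — fraction of positives containing the feature at
  least once;
* **fold-enrichment** — epitope coverage divided by background coverage,
  *missing* when no background molecule contains the feature (a ratio
  with a zero denominator carries no information);
* **mean count difference** — mean count among feature-containing
  positives minus mean count among feature-containing background
  molecules (sign convention: positive means epitopes carry more copies),
  *missing* under the same condition; when no positive contains the
  feature the positive-side mean is taken as zero.

Missing values are kept as explicit `NA` and rendered `-` in text
reports. Reports of the top features (default at most 8) attach the
substructure fragment resolved on an example molecule — the containing
positive with the lowest identifier, falling back to any containing
molecule for background-enriched features.

## The prediction report

`predict()` on a fitted pipeline performs the two-step analysis for a
query SMILES: cluster assignment via the folded non-chiral encoding, then
per-assay probability from that cluster's random forest on the query's
count fingerprint restricted to the cluster's feature registry. Query
features unseen in training are dropped — the registry defines the
model's input space — and their number is reported so out-of-domain
queries are visible. A cluster with no positives for an assay yields `NA`
probabilities and an explanatory note rather than a fabricated score. The
report also lists the significant enriched features the query contains
and its five nearest stored epitopes, ranked by Euclidean distance over
the cluster's retained feature counts with the overall count-Tanimoto (on
full unfolded fingerprints) shown alongside — two deliberately different
spaces: the first is the model's geometry, the second a
registry-independent whole-molecule similarity.

## The synthetic generator

Real training data for this problem comes from curated epitope and
chemical-entity databases that cannot be bundled. The generator
(`synthetic_spec()` / `generate_molecules()`) emulates the *signal
structure* instead: scaffold templates (pyranose, arene, glycerol-like,
fatty acid) carry an unbranched carbon chain of class-dependent sampled
length at one site — the repeated-CH2 count signal — plus a random small
decoration at a second site so that canonical deduplication keeps the set
intact. An optional planted motif (default an ethyl-phosphate fragment)
attaches to positives with probability q. Labels satisfy the declared
rule (chain length threshold, motif presence, or either) *exactly*; specs
whose chain ranges contradict the rule are rejected rather than silently
relabeled. Identical seeds give byte-identical datasets.

What the generator does **not** emulate: real structural diversity
(rings beyond the fixed scaffolds, stereochemistry-rich sugars, salts),
label noise, assay heterogeneity, and database curation bias. Passing
tests on generated data therefore demonstrate that the machinery recovers
planted signals of the right *kind* — count-borne, substructure-local —
not that any particular real-data accuracy will be reached.

## Numerical choices and problem sizes

* Feature identifiers are 32-bit unsigned hashes stored as R doubles
  (exact below 2^53); the hash is a fixed polynomial combine, so encodings
  are platform-independent.
* Degenerate inputs have defined behavior throughout: empty reference
  sets, single-class labels, zero-variance features, rank-deficient PCA
  input (zero coordinates, zero variance fractions), clusters with no
  surviving features (absent models plus a note).
* The null-model calibration in the acceptance script uses a 500-molecule
  dataset (10% positives). This size keeps at least 10 positives in every
  CV fold, where the chance-level AUC estimator (mean of 75 fold AUCs
  over 5 seeds) has a between-seed standard deviation of about 0.025 —
  comfortably inside the ±0.05 acceptance band. At 300 molecules the same
  estimator wanders with sd ≈ 0.055, which says nothing about leakage,
  only about fold-level noise with 6 positives per fold.
* Unit and property tests run at small n (tens to a few hundred
  molecules, k ≤ 4) chosen so the full suite completes in well under a
  minute of pure computation per file.

## Known limitations

* Canonicalization and aromaticity perception are delegated to OpenBabel;
  molecules OpenBabel cannot parse are rejected, and exotic elements
  outside the supported table raise an explicit error.
* Chirality handling distinguishes stereocenters as written in canonical
  SMILES; it is not a CIP engine, and cis/trans double-bond isomerism is
  ignored by design.
* Greedy correlation pruning keeps the first feature of a correlated
  group in scan order, which is arbitrary (though deterministic); the
  enrichment tables are computed after pruning, so a pruned feature's
  signal appears under its surviving proxy.
* k-means on binary fingerprints inherits k-means' geometry: clusters are
  convex in the folded space, and molecules with few set bits aggregate
  regardless of chemistry.
* The per-cluster random forests are only as good as the cluster's
  positive count; clusters with a handful of positives produce
  high-variance probabilities, which is why the report always shows the
  nearest stored epitopes next to the score.
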