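---
title: "Predicting mannose-interacting residues from sequence windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mannose-interacting residues from sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsvm)
```

## The problem

Mannose-binding lectins recognize mannose displayed on pathogen surfaces;
the residues that actually contact the sugar — mannose-interacting residues
(MIRs) — are a small minority of a chain (roughly 1 in 38 residues in
curated complex-derived data). `mirsvm` predicts, for every residue of a
protein sequence, whether it is a MIR. The package covers the full path
from structure to prediction: contact-based labelling, window generation,
three feature encodings, an RBF support-vector machine with asymmetric
class cost, threshold-swept evaluation under five-fold cross-validation,
and compositional enrichment analyses.

## From structure to labels

A residue is labelled interacting when any of its heavy atoms lies within a
distance cutoff (default 4.0 Å, inclusive) of any heavy atom of a mannose
residue. Choices a contact definition must make, and our defaults:

* **Ligand identity** is by PDB residue name, default `MAN` (α-D-mannose)
  and `BMA` (β-D-mannose), configurable for glycan variants.
* **Heavy atoms only** (element ≠ H/D): crystal structures rarely resolve
  hydrogens and contact practice is heavy-atom based.
* **Alternate locations**: the highest-occupancy conformer is kept, ties
  broken by altloc identifier; multi-model files contribute model 1 only;
  waters never count as protein or ligand.
* Unknown 3-letter residue names map to the dummy residue `X` with a
  warning, so real PDB-derived chains remain usable.

Labelled chains travel as case-annotated FASTA: lowercase = interacting.
`make_toy_complex()` builds synthetic complexes in which the
contact set is known exactly by construction; the test suite checks the
annotator against a brute-force all-pairs distance scan on a hundred such
complexes.

## Windows and encodings

Every residue is classified from the fixed-length window centered on it
(L odd, default 17; 17–25 are the sensible range). Termini are padded with
(L−1)/2 dummy `X` residues per side, so a chain of length n yields exactly
n windows and terminal residues are predicted like any other. The alphabet
is fixed and documented (`mir_alphabet()`): the 20 standard amino acids in
alphabetical one-letter order, then `X` — all encodings index against it,
so feature vectors are stable across versions.

* **Binary profile (`bpp`)** — one-hot per position, L × 21 values. Order-
  sensitive, sparse (17 ones among 357 zeros at L = 17).
* **PSSM profile (`ppp`)** — per-position rows of a PSI-BLAST
  position-specific scoring matrix, normalized to [0, 1]. The published
  source for this design renders its normalization formula illegibly, so the
  package makes the choice explicit: the default is the logistic map
  1/(1+e^−x) — strictly increasing, bounded, and robust to the very wide
  (±1000) dynamic range of raw log-odds — with matrix-wide min-max scaling
  available as `method = "minmax"`. Padded positions contribute a one-hot
  `X` row; the `X` column's raw score is defined as 0. The reader consumes
  the PSI-BLAST ASCII dialect (`-out_ascii_pssm`) and reorders its columns
  to the package alphabet; running PSI-BLAST itself is out of scope.
* **Composition profile (`cpp`)** — the 21-component composition of the
  window, comp(i) = Rᵢ/N with N = L including padding, so components always
  sum to 1. Order-free and dimension-free in L: the encoding a compositional
  binding signal is best matched by.

## Datasets, the SVM, and its parameters

`build_main_dataset()` keeps all positive windows and samples an equal
number of negatives uniformly without replacement (seeded);
`build_realistic_dataset()` samples `ratio` (default 10) negatives per
positive instead, approximating the natural imbalance. Positives come
first, then sampled negatives in chain order; fold shuffling happens in
cross-validation.

The classifier is a C-SVC with RBF kernel (backed by libsvm via `e1071`),
parameterized as:

| parameter | meaning | default |
|---|---|---|
| `g` | RBF kernel width γ | 0.01 |
| `c` | training-error/margin trade-off | 2 |
| `j` | cost factor on positive-class training errors | 2 |

`j` multiplies the misclassification penalty of positive examples
(`class.weights` in libsvm), the standard lever for imbalanced data: larger
`j` buys sensitivity at the cost of specificity, which the tests verify as
a monotone property. Decision scores are oriented so positive values favor
the interacting class; classification at threshold t is score ≥ t, and the
default sweep is −1 to +1 in steps of 0.1.

One numerical caveat the package documents rather than hides: γ must match
the feature scale. Composition vectors live on a 1/L grid, with typical
pairwise squared distances of 0.02–0.1, so γ = 0.01 — a reasonable value
for the sparse binary profile, whose squared distances reach 2L — leaves
the RBF kernel nearly constant on composition features. For the synthetic
benchmark below the composition models therefore use γ = 50 (chosen by a
coarse grid on probe data) while binary models keep γ = 0.01.
`grid_search()` automates this per dataset.

## Evaluation

`metrics_from_counts()` computes Sen = 100·tp/(tp+fn),
Spe = 100·tn/(tn+fp), Acc, and the MCC, defined as 0 when any denominator
factor vanishes; absent classes flag rates as `NA` rather than silently
zeroing them. Counts may be fractional: `metrics_from_rates()` rebuilds
tp = sen·n₊/100 and tn = spe·n₋/100 from printed percentage pairs, which
lets published per-threshold tables be verified to two decimals without
integer-rounding artifacts (rounding is half-up and applied only at
display).

`five_fold_cv()` stratifies folds by class, so per-class fold sizes differ
by at most one in any dataset; every fold is tested once against a model
trained on the other four, and per-threshold metrics are averaged over
folds (the headline protocol), with pooled-score metrics and the pooled
ROC/AUC also reported. The ROC steps only after the last of a run of tied
scores, making the trapezoidal AUC equal the Mann–Whitney U statistic over
n₊·n₋ to machine precision — an identity the tests assert directly and
cross-check against an independent implementation.

## The synthetic-data generator

`generate_chains()` emulates the statistical structure the predictor
exploits, with defaults fixed once:

* chain lengths uniform on 80–250; target interacting fraction 0.027
  (≈ 1 MIR per 37 non-MIRs, the natural scarcity in complex-derived data);
* interacting positions placed as non-overlapping clusters of 1–4
  consecutive residues (binding pockets are local); cluster geometry is
  configurable;
* at interacting positions, residues drawn with a 5× up-weight on
  D, E, N, Q, R, S, T, W, Y — the set enriched at mannose contacts
  (polar/uncharged side chains plus the CH/π aromatics Trp and Tyr);
* within ±3 of an interacting position, a 3× up-weight on S, T, G;
* background uniform unless given. Biases accept per-letter weight vectors,
  which the tests use to check that composition analysis recovers a graded
  enrichment ranking (Spearman > 0.9 against the sampling weights).

What the generator does **not** emulate: real evolutionary profiles (its
toy PSSMs are smoothed one-hots plus noise, labelled synthetic), 3D surface
geometry, sequence redundancy, or inter-position correlations beyond the
cluster/flank structure. Passing end-to-end tests therefore demonstrate
that the pipeline detects compositional signal of realistic strength and
invents none where there is none — not that real-data accuracies transfer.

`make_end_to_end_fixture()` packages three study conditions (100 training
chains by default): `easy` (center 8×, flank 4×) on which the
cross-validated composition model reaches MCC ≈ 0.5–0.6 at threshold 0 and
outperforms the binary profile; `hard` (1.5×/1.2×); and `null` (no bias).

**A leakage subtlety worth knowing.** With clustered interacting sites,
windows centered on neighboring cluster members are near-duplicates; random
pattern-level folds then place siblings on both sides of the train/test
split, and even zero-signal data can show apparent MCC ≈ 0.4. This is a
real artifact of pattern-level cross-validation on overlapping windows —
the protocol this package reproduces — and users evaluating on their own
data should consider chain-level splits. Within the package, the `null`
fixture uses isolated single-residue sites so the no-signal control
measures encoder-driven signal rather than window duplication; the
no-signal MCC is measured on 200 chains, where its sampling noise is
sd ≈ 0.025 around a small negative bias (an overfit kernel machine ranks
unseen positives slightly low, AUC ≈ 0.47).

## Degenerate inputs and numerical choices

* Even or non-positive window lengths, single-class training data, feature
  dimension mismatches, malformed PSSM rows, and structures without protein
  chains are errors, not silent repairs.
* Nonstandard residue codes (B, Z, U, O, J) map to `X` with a warning at
  every entry point.
* Fewer available negatives than requested keeps them all with a warning.
* The distance cutoff comparison is inclusive (≤); composition sums are
  asserted to 1 within 1e−9; AUC identities to 1e−9.
* All sampling (negatives, folds, generator) is seeded; identical seeds
  reproduce datasets, scores and reports byte-for-byte, which both the test
  suite and the acceptance script assert.

## Problem sizes used in checks

The packaged checks run on deliberately desk-scale inputs: fixtures of
100–200 chains of 80–160 residues (≈400–850 patterns per dataset), 100
random toy complexes for the contact oracle, and 50 random score sets for
the AUC identity. These sizes put the measured quantities' sampling noise
well inside the asserted bands while keeping the whole suite and the
acceptance script in the tens of seconds on a single CPU.

## Known limitations

* Real-data headline accuracies require the original curated complexes and
  PSI-BLAST profiles; the package validates the machinery, not those
  numbers.
* The similarity-search baseline and redundancy reduction (BLAST/BLASTclust)
  are upstream tools whose outputs the package consumes, not features.
* mmCIF structures are not read; convert to PDB first.
* Pattern-level cross-validation optimistically scores clustered sites (see
  above); chain-grouped evaluation is recommended for real data.
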