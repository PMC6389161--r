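---
title: "Predicting crystallization pipeline outcomes from sequence"
author: "crystalprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting crystallization pipeline outcomes from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystalprop)
```

## The model

Protein production and crystallization pipelines annotate every target with
a terminal outcome: material production failed (MF), purification failed
(PF), crystallization failed or the crystals diffracted poorly (CF), or a
diffraction-quality crystal was obtained (CR). `crystalprop` treats these as
four separate one-vs-rest binary problems and fits one logistic regression
per outcome on features computed from the sequence alone. The deliberate
restriction to alignment-free features keeps prediction effectively
instantaneous per protein, which is the regime in which such a predictor is
used — triaging thousands of candidate targets.

The assumptions are therefore: (i) the outcome signal available to the model
is entirely compositional/physicochemical (no evolutionary profiles, no
structural templates); (ii) the four outcomes are modelled independently —
no multinomial coupling, no shared calibration; (iii) inter-molecular
determinants of crystallization (buffers, tags, constructs) are outside the
model's domain.

## The feature space

A validated chain maps to an ordered vector of 1276 features, asserted at
catalog construction (420 + 336 + 448 + 4 + 68):

* **Composition (420).** 20 single-residue frequencies and 400 dipeptide
  frequencies; each block sums to 1.
* **Grouped C/T/D (336).** Seven three-class physicochemical alphabets
  (hydrophobicity, van der Waals volume, polarity, polarizability, charge,
  secondary-structure propensity, solvent accessibility; see
  `propertyAlphabets()`). Per property, 48 features: class composition (3),
  normalized unordered class-pair transition frequencies (3), the positions
  of the 1st/25%/50%/75%/last occurrence of each class divided by the
  length (15; 0 for an absent class — the models require finite fixed-length
  vectors, so "absent" is encoded as 0 rather than missing), and nine
  segment statistics per class (27).
* **Residue-index profiles (448).** 64 hydrophobicity/energy-themed
  per-residue scales shipped as a plain-text table
  (`residueIndexTables()`). Per scale: whole-chain mean plus windowed
  min/max of window means for windows 5, 15 and 31. Windows longer than the
  chain are clipped to a single whole-chain window so that a length-30
  sequence still produces the window-31 features.
* **Whole-chain indices (4).** Isoelectric point (bisection of the
  Henderson–Hasselbalch net charge on pH 0–14 to 1e-3), aliphatic index,
  instability index (bundled dipeptide-weight table), and net charge at
  pH 7. The bundled pKa set (N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1,
  H 6.5, K 10.8, R 12.5, Y 10.1) is a fixed documented choice; published
  titration sets differ by a few tenths of a pH unit and any consistent set
  yields equivalent features.
* **Complexity/disorder summaries (68).** Two per-residue signals — a
  windowed hydropathy–charge disorder score and a windowed Shannon-entropy
  low-complexity mask (window 12, threshold 2.2 bits) — each collapsed by
  the same fixed 34-statistic summary (`profileSummary()`). Both signals
  are deterministic built-ins; an externally computed per-residue score can
  be injected from a two-column text file and is used verbatim after
  clipping to [0, 1]. The built-in disorder score is intentionally simple
  (charged/low-hydropathy windows score high); it is a feature source, not
  a disorder predictor in its own right.

The per-group internal layouts (48 per property, 7 per scale, 34 per
signal) are fixed package contracts; the binding structural constants are
the group totals, which the catalog validates on construction.

## Feature selection

Per outcome, three stages:

1. **Relevance.** Keep feature *j* iff |r<sub>j</sub>| ≥ 2 × mean |r|,
   where r is the point-biserial correlation with the outcome label
   (computed as Pearson against the 0/1 vector; a constant feature gets 0).
   Absolute correlations are used: a strongly negative feature is as
   relevant as a strongly positive one. Because the rule is relative it can
   keep arbitrarily few features on homogeneous spectra, so a ranked
   top-`minRetained` (default 10) fallback guarantees the wrapper has
   material to work with.
2. **Redundancy.** Scanning survivors by descending |r|, a feature is kept
   only if its absolute Pearson correlation with every already-kept feature
   is ≤ 0.7 — the more relevant member of a correlated pair survives, which
   preserves the ranking semantics for the wrapper.
3. **Wrapper.** Initialize with the top-ranked candidate, scan the rest
   once in rank order, and accept a candidate iff it strictly improves the
   mean out-of-fold AUC of the logistic model under stratified 5-fold
   cross-validation (folds fixed for the whole scan, assignment seeded).
   Strict improvement with no epsilon means ties reject, biasing toward
   smaller models. There is no revisiting and no backward elimination.

The accepted-AUC sequence is strictly increasing by construction and is
recorded, with every rejected candidate, in the `SelectionResult` trace.

## Model fitting and calibration

Features are standardized to zero mean/unit variance (constant features get
scale 1) and fitted by IRLS from a zero start, so training is deterministic
given the data; convergence is declared when the largest coefficient change
drops below 1e-8 (at most 100 iterations). Separated or quasi-separated
data — detected as non-convergence or standardized coefficients diverging
past 30 — trigger a refit with a tiny ridge (1e-4) on the standardized
weights, reported via a message and recorded in the model. The test suite
cross-checks the fit against `stats::glm` on non-separated data.

Confidence tiers are calibrated on the training propensities: `low` below
the 20th percentile, `high` above the 80th, `medium` otherwise (strict
inequalities; linear-interpolation percentiles). On a continuous
propensity distribution the training data split 20/60/20 by construction;
with heavily tied propensities (e.g. a near-separated fit) the tiers
degenerate gracefully toward `medium`.

The overall call per protein is the highest-propensity outcome; exact ties
resolve toward the later pipeline stage (MF < PF < CF < CR), a deterministic
convention favouring the optimistic call.

## Evaluation protocol

`bootstrapEvaluate()` draws subsets of `round(0.25 n)` **without**
replacement — the protocol is subsampling ("randomly chosen proteins"), not
the classical with-replacement bootstrap — and reports mean ± sd of AUC,
MCC and accuracy over 100 replicates by default. Single-class subsets are
redrawn (bounded retries) so the replicate count stays fixed. MCC and
accuracy binarize at a 0.5 threshold by default; the threshold is exposed
because a tuned cutoff is equally defensible. Paired t-tests and the
Anderson–Darling normality check (via `nortest`, decision at α = 0.05)
support comparisons between bootstrap metric vectors, and
`pearsonCorrelation()` compares propensity vectors between predictors.

## Trial-status annotation

`mapStatus()` maps registry status strings to outcomes by normalized exact
match (case-folded, whitespace-collapsed) — substring matching would
over-capture free-text statuses. The CR synonyms from different registry
eras ("PDB duplication found", "PDB duplicate found", "TargetDB duplicate
target found", plus the current statuses "crystal structure" and "in PDB")
live in one editable table (`statusMap()`). `resolveFarthest()` keeps, for
a sequence with several trials, the outcome farthest into the pipeline: a
later-stage record proves the earlier stages succeeded. Similarity-based
redundancy reduction between sequences (25%-identity clustering) requires
an external clustering tool and is deliberately left to the user.

## The synthetic-data generator

`syntheticProteinSet()` draws sequences residue-by-residue from class-
specific compositions: uniform 1/20 perturbed by `effectSize` along fixed,
zero-sum per-class direction vectors (MF toward hydrophobic/aromatic
residues, PF toward charged, CF toward repeat-prone, CR toward
small/ordered ones — loosely motivated by published crystallizability
trends, with no claim of realism). Lengths are log-normal (median 300,
sdlog 0.45 — the scale of a typical structural-genomics target) clipped to
[30, 2000] so every sequence passes validation. Extreme effect sizes clip
negative probabilities and renormalize, with a message.

What the generator emulates is exactly the signal family the model can
express: class-dependent composition. What it does **not** emulate is the
weak, heterogeneous, partly non-compositional signal of real trial data —
real outcome prediction from sequence achieves AUCs around 0.6–0.75, not
the ≈1.0 the pipeline reaches at `effectSize = 0.5`. Passing end-to-end
tests therefore demonstrate that the machinery recovers learnable structure
and stays at chance on null structure; they say nothing about real-data
accuracy, which requires real trial annotations.

`syntheticFeatureTable()` generates feature matrices with a known logistic
generative model for the recovery tests: standardized-weight recovery
within 5% at n = 20 000 (weights ±1.2, a regime where the asymptotic
standard error ≈ 0.02 leaves comfortable margin), and wrapper recovery of
all informative columns in ≥ 18/20 seeded runs at n = 5000.

## Numerical and design choices

* Percentiles: linear interpolation between order statistics
  (`quantile type 7`), strict tier inequalities.
* pI bisection on [0, 14] to 1e-3 pH; the charge model uses side chains
  D, E, C, Y, H, K, R plus free termini.
* AUC uses midranks, so tied scores contribute 0.5 per pair.
* Point-biserial of a constant feature is defined as 0 rather than NA so
  relevance filtering never propagates missingness.
* All randomness (fold assignment, bootstrap draws, generators) flows from
  explicit integer seeds; stage sub-seeds are derived deterministically, so
  every pipeline product is bit-reproducible.
* Problem sizes in the shipped checks — 400 proteins per class end-to-end,
  n = 20 000 for weight recovery, 20 seeded wrapper runs — were chosen as
  the smallest sizes at which the statistical assertions have comfortable
  margins; each end-to-end run takes on the order of a minute on a single
  core.

## Known limitations

* The bundled residue-index set and the internal layouts of the grouped and
  profile summaries are documented package choices; other implementations
  of the same feature families will differ in detail while preserving the
  group totals.
* The built-in disorder and complexity signals are fast approximations;
  injecting scores from dedicated predictors will change the 68 summary
  features.
* No regularization path: the wrapper plus plain logistic regression is the
  entire capacity control, as in the original design; very wide synthetic
  feature sets with weak signal can accept several noise features (held-out
  performance stays near chance, as the null end-to-end check asserts).
* Training data must contain both classes for every outcome; the package
  does not handle the degenerate single-class case beyond a clear error.
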