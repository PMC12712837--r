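---
title: "Sparse PLS blood-brain signatures: models, choices, and what the synthetic benchmarks show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse PLS blood-brain signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbspls)
```

## The problem and the model

Studies linking peripheral blood markers to brain structure ask a
multivariate question: which weighted combination of blood parameters
covaries, across participants, with which weighted pattern of voxelwise
gray-matter volume (GMV)? With ~20 blood features against tens of
thousands of voxels, classical CCA overfits catastrophically; sparse
partial least squares (SPLS) answers it with a penalized rank-1 SVD of
the cross-product matrix. For standardized views $X$ (n × p blood) and
$Y$ (n × q brain), one latent variable (LV) is the pair

$$\max_{u, v}\; u^\top X^\top Y v
\quad \text{s.t.} \quad \|u\|_2 = \|v\|_2 = 1,\;
\|u\|_1 \le c_u,\; \|v\|_1 \le c_v,$$

solved by alternating exact updates: each half-step is the joint L1/L2
projection of $M v$ (or $M^\top u$), i.e. an L2-normalized
soft-thresholded vector whose threshold is chosen so the L1 budget is
met. Because each half-step solves its subproblem exactly, the objective
is non-decreasing, which the implementation asserts at every sweep.
Budgets live on the usual penalized-matrix-decomposition scale
$[1, \sqrt{\text{dim}}]$: 1 forces a single nonzero weight,
$\sqrt{\text{dim}}$ deactivates the constraint.

A participant's *latent scores* are the projections $X u$ and $Y v$; the
correlation between the blood and brain score vectors measures the LV's
strength and is the out-of-sample criterion throughout. Successive LVs
are extracted after *projection deflation* $X \leftarrow X(I - uu^\top)$,
$Y \leftarrow Y(I - vv^\top)$, which makes later scores exactly
orthogonal to earlier weight directions.

## The two-level pipeline

**Level 1** (`extract_model()`) embeds the SPLS core in a
group-stratified nested cross-validation. Outer folds (default 10)
estimate the out-of-fold latent-score correlation `rho_test`; inner
folds (default 10) select the sparsity budgets; *all* preprocessing —
median imputation of the blood view, ComBat harmonization of the brain
view across scanners, and z-scoring — is refit inside every training
partition, so no test-fold statistic ever reaches a fitted state.
Significance is a permutation test that breaks the blood-brain row
linkage; feature stability is assessed by bootstrap ratios
(mean/SE of each weight over row resamples, |BR| ≥ 2 flagged stable);
significant LVs are deflated out and extraction continues until the
first non-significant LV. `project_replication()` pushes an independent
sample through the stored preprocessing and deflation chain and reports
per-LV replication correlations with score-permutation p-values.

**Level 2** (`assign_quartile_groups()`, `classify_signature()`)
explores an extracted signature: participants with *both* latent scores
strictly above the 75th percentile are high scorers, both strictly below
the 25th percentile low scorers (linear-interpolation percentiles;
strict inequalities keep the groups disjoint under ties). A
linear-kernel SVM with inverse-frequency class weights classifies high
vs low scorers from clinical predictor domains inside a repeated nested
CV (10 folds, 10 repetitions; cost selected on inner folds by balanced
accuracy over a geometric grid spanning 1e-3…1e3). Significance uses
label permutations (the reference design uses 5000); per-feature
relevance uses sign-based consistency: the fraction of fold models in
which a weight keeps the majority sign, combined with the mean normalized
weight into a stability score, calibrated against label-permutation
refits and Benjamini-Hochberg-adjusted across features (a plain
binomial(0.5) test of the sign counts is also available; see below).

## The synthetic-data generator

Real cohorts of this kind are not publicly deposited, so the package
ships a first-class generator (`truth_spec()`, `simulate_dataset()`)
whose defaults define the study conditions used by the test suite:

* n = 400 participants in four diagnostic groups (ROD/ROP/CHR-P/HC) at
  the proportions of a 678-participant early-psychosis cohort
  (163/177/172/166), recruited across 3 sites;
* p = 20 blood features, q = 2000 voxels (preserving the p ≪ q
  asymmetry at desk scale);
* K = 2 planted LVs with latent-score correlations ρ* = 0.50 and 0.35,
  drawn per participant from a bivariate normal; optional per-group mean
  shifts on both members (default zero, so ρ* is exactly the latent
  correlation);
* planted weights with disjoint supports (5 blood features, 100 voxels
  per LV), support magnitudes sign·U(0.5, 1.5) then normalized —
  bounded away from zero so that support recovery is well defined;
* additive per-site, per-voxel scanner offsets with SD 0.5, drawn once
  with the spec so discovery and replication draws share scanners
  (`replicate_spec()` changes the sampling seed, not the truth);
* residual noise SD 0.2 in both views, and 10% missingness, completely
  at random, in the blood view only (voxel maps are complete per scan;
  the cohort inclusion rule caps missingness at 20%).

Predictor tables emulate three clinical domains — psychosocial (43
features), neurocognition (7), medication (4). Informative columns
differ between the eventual quartile-conjunction high and low scorers by
a standardized mean difference (default d = 1; medication is generated
with zero planted effect, mirroring the null medication finding the
two-level design is meant to expose).

What the generator does *not* emulate: realistic cytokine
distributions and assay noise, spatial voxel correlation, MRI physics,
site-by-covariate confounding, and informative missingness. Passing
benchmarks therefore show that the estimation machinery recovers planted
low-rank cross-view structure under site effects and MCAR missingness —
not that any particular clinical finding would replicate.

## Design choices in the open

**Budget selection vs consolidation.** Inner folds select the budget
maximizing the mean out-of-fold |correlation| (ties toward sparser
budgets). For the final full-sample refit the per-fold selections must
be consolidated, and here a plain mode or argmax is unreliable for a
structural reason: out-of-fold *correlation* saturates once a handful of
informative voxels carry the latent score — a 15-voxel fit with weight
cosine ≈ 0.4 to the true pattern predicts scores as well as a
full-support fit with cosine ≈ 0.9 — so the correlation surface is a
flat ridge and its argmax wanders. Out-of-fold *covariance*, the
quantity SPLS itself maximizes, does discriminate: it keeps growing with
support coverage and gains nothing out of sample from noise voxels. The
consolidation rule is therefore: among budgets within two standard
errors of the pooled correlation optimum, take the one with the largest
pooled out-of-fold covariance (then sparser). In recovery experiments on
the default generator this rule selects the budget with the best weight
recovery in essentially every draw, where the alternatives (fold-modal
budget, pooled argmax, one-SE-sparsest) each failed on a noticeable
fraction of draws. The fold-modal rule remains the fallback when no
inner surfaces exist (single-point grids).

**Permutation design.** The null is "no blood-brain association", so
whole rows of the blood view are permuted and the out-of-fold statistic
is recomputed with per-fold preprocessing refit on the permuted data.
By default each permutation reuses the per-fold budgets selected on the
observed data; `reselect_perm = TRUE` reruns the full inner search per
permutation at ~grid-size times the cost. P defaults to 999;
`p = (1 + \#\{\rho_{perm} \ge \rho_{obs}\}) / (P + 1)`, never zero.
`extract_model()` uses sequential early stopping (stop once the
exceedance count h = ⌈α(P+1)⌉ is reached, reporting h/b — the
Besag-Clifford Monte-Carlo p-value), which leaves significant LVs
untouched and spares most permutations on the terminating null LV.

**Harmonization.** ComBat-style location/scale adjustment with
parametric empirical-Bayes shrinkage, fit strictly on training data and
applied to held-out samples via the stored estimates (the fit/apply
split standard ComBat implementations do not expose). Diagnostic group
is preserved as a covariate by default; EB and the covariate are config
switches. Single-site data is a warned no-op; unseen sites pass through
with a warning.

**Other numerical choices.** Threshold search in the L1/L2 projection
solves the normalized-L1 crossing segment exactly on the sorted
magnitude path (closed-form prefix sums plus bisection on an O(1)
expression), so projections are exact to machine precision and the
alternation is genuinely monotone. Initialization is the leading right
singular vector of M (deterministic; computed via the small-side Gram
matrix). Sign convention: the largest-|u| blood weight is positive,
v flipped jointly. Convergence is declared on weight change (< 1e-6
max-abs), not objective change, to avoid plateau false positives;
non-convergence warns and returns the current pair. Degenerate folds
(zero-variance scores) contribute correlation 0 with a warning.
Boundary ties in quartile grouping are excluded by strict inequality.
Bootstrap resamples that produce a constant column are skipped and
counted; weights with zero bootstrap spread get BR = 0 (zero mean) or a
signed infinite sentinel (nonzero mean, maximally stable).

## Problem sizes used by the shipped benchmarks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the whole suite completes in tens of minutes on one core: the
default generator (n = 400, q = 2000) with 10 outer × 4 inner folds, a
4 × 6 budget grid, P = 99 permutations and B = 100 bootstrap resamples
for the 20-seed recovery study; 200 null studies at n = 100, q = 200
for permutation calibration; and SVM fixtures with 50-60 participants
per class. The method defaults (10 × 10 folds, 8 × 8 grid, P = 999,
B = 500, 5000 label permutations) are what an analysis of a real cohort
would use.

## Known limitations

Linear associations only (no kernelized SPLS); two views only; the
permutation scheme ignores site/group structure under the null (config
switches document this); the binomial variant of sign-based consistency
treats fold models as independent, which overlapping training folds
violate — on planted-null experiments it flags most noise features, which
is why `classify_signature()` uses the permutation-calibrated mode (each
feature's stability score z-scored against its own label-permutation null
moments) and the binomial variant should be read as a ranking; and the
generator's
independence assumptions (no voxel autocorrelation, MCAR missingness)
are idealizations of real imaging data.
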