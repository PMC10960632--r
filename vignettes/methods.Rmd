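---
title: "Measuring item- and category-level neural distinctiveness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring item- and category-level neural distinctiveness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patsim)
```

This vignette is the package's own account of the science it implements:
the measurement model, its assumptions, the tunable parameters, the
synthetic data generator, and the numerical and design choices that were
genuinely open. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The experimental design being modelled

The analysis targets a two-session encoding paradigm with a subsequent
recognition test. In a first target-detection phase (TD1) participants
view 320 objects over three runs (106/107/107) followed by 60 scenes in
a fourth run; 20 objects and 10 scenes are response targets and are
excluded from all similarity analyses. Of the remaining objects, 250 are
paired with the 50 non-target scenes (five objects per scene) in an
intervening associative task, and 50 are baseline items. A second
target-detection phase (TD2) re-presents all 320 objects over three
runs. At retrieval, the 250 paired objects return on a matching
(n = 100), mismatching (n = 100) or new (n = 50) scene, intermixed with
150 new objects; participants judge item old/new and pair old/new. Run
labels are globally unique (TD1: 1–4, TD2: 5–7, retrieval: 8), so the
cross-run rule below is a single comparison.

`generate_design()` reproduces this structure for arbitrary counts.
Pseudorandomisation is a uniform shuffle under the seed: exact run-assignment
constraints of such tasks are rarely reported, and no first-order
balancing is imposed. Item recognition has an analytical
chance level of `p(old) × n_old / n_total`, i.e. 0.5 × 250/400 = 0.3125
("0.31"), and response bias is FAR / (1 − (HR − FAR)). At the corner
HR = 1, FAR = 0 that formula is 0/0; `response_bias()` returns 0 there
(zero numerator, by continuity), which is the only point where the
denominator can vanish for rates in [0, 1].

## Trial-wise beta estimation (least-squares-single)

Each trial's activation image is estimated with its own GLM: one
regressor for the target trial, one for all other trials in the same
run, six motion regressors when available, one indicator for the first
three dummy volumes, and an intercept. Events are impulse ("stick")
functions at stimulus onset convolved with the canonical double-gamma
HRF (peak delay 6 s, undershoot delay 16 s, dispersions 1 s, ratio 1/6,
32 s support, unit-sum normalised — peaking near 5 s). The 2.307 s
stimulus duration is not modelled as a boxcar, matching the
stick-function convention; no HRF derivatives, prewhitening or high-pass
filtering are applied (the synthetic data carry no drift, and the
estimator deliberately stays minimal). An implicit
mask retains voxels whose mean signal exceeds 0.4 × the grand mean of
voxel means; the reference intensity had to be fixed here since only the
0.4 fraction is conventional — the grand mean over the initial mask is
the SPM-style reading.

A caveat documented by the tests: LSS is an approximation whenever the
amplitudes of the *other* trials differ, because one shared regressor
cannot represent them all. The self-inversion oracle therefore uses
two-trial runs (where the LSS model spans the generating model exactly,
even with overlapping responses); recovery there is exact to numerical
precision, and with >2 distinct-amplitude trials a small systematic
residual (~1e-3 at typical spacings) is inherent to the method, not a
bug.

## Searchlight similarity metrics

Patterns are compared by Pearson correlation across voxels, Fisher
z-transformed (`atanh`) *per pair* and then averaged; r is clipped at
1 − 1e-7 so identical synthetic patterns stay finite. Similarity is only
computed between trials from different runs, to avoid time-dependent
correlation of haemodynamic responses within a run.

* **Item level** (cross-phase, hence automatically cross-run):
  within-item = mean z-correlation of each object's TD1 pattern with the
  same object's TD2 pattern; between-item = mean over all TD1 × TD2
  object pairs excluding the same-object pairs. TD1×TD1 and TD2×TD2
  object pairs are *not* used at this level — the metric is defined
  cross-phase only.
* **Category level** (TD1 only, since scenes appear only there):
  within-category = mean z over object–object pairs from different TD1
  runs; between-category = mean z over all object–scene pairs (cross-run
  by design).
* **Scene-pairing controls**: (within-scene − between-scene) object
  similarity per phase, contrasted TD2 − TD1, optionally restricted to
  objects with correct pair memory or to strong-memory scenes (3–5 of a
  scene's five pairs remembered vs 0–2).

Searchlights are spheres of 4 mm radius on the voxel lattice (33 voxels
at 2 mm isotropic); the centre is always a member. Centres are required
to be in-mask; neighbourhoods are truncated at the mask and volume
edges, and a centre with fewer than `min_voxels` (default 5) valid
neighbours is invalidated — the edge-handling convention had to be
chosen here, and truncation-with-a-floor is the least surprising one.
Group analyses use only voxels valid in every subject
(`group_valid_mask()`). Missingness is mask-level: the implicit mask is
shared by all trials of a subject, so pairwise-complete handling of
per-trial missing voxels never actually triggers with the shipped
generators.

The implementation aggregates sliding sums, sums of squares and
cross-products over the sphere with one sparse incidence-matrix multiply
per chunk of trial pairs, which makes the per-centre correlation exactly
the textbook formula while avoiding a per-centre loop. Every map is
checked against an independent brute-force double loop (nested over
centres and pairs) to 1e-12 in the test suite.

Trial-wise distinctiveness (for memory analyses) uses a cluster mask as
one pattern — no sub-searchlights — mirroring the back-projection of
group clusters into subject space: item level,
`z(r(TD1_i, TD2_i)) − mean_{j≠i} z(r(TD1_i, TD2_j))`; category level,
`mean_{j≠i, run≠} z(r(TD1_i, TD1_j)) − mean_s z(r(TD1_i, scene_s))`.
The subject mean of trial-wise item values equals the mask-level
within-minus-between difference exactly (equal partner counts), which
the tests exploit as an aggregation identity.

## Cluster-mass permutation inference

Voxelwise contrasts are dependent-samples t tests (one-sample on
condition differences) or pooled-variance independent-samples t tests
(classic neuroimaging practice; Welch is deliberately not the default).
Voxels significant at two-sided p < 0.005 (0.01 for control analyses)
are grouped into sign-separated connected components — 26-connectivity
by default, configurable, since "adjacent" is ambiguous in 3-D — and
each cluster's mass is the sum of its member t values. The null is the
distribution of the *maximum* absolute cluster mass over permutations
(dependent: per-subject condition swaps, i.e. sign flips of the
difference maps; independent: group-label shuffles preserving group
sizes), the FieldTrip-standard max-statistic convention that controls
family-wise error across clusters. Cluster p values use the add-one
rule `p = (1 + #{null ≥ |mass|}) / (n_perm + 1)`, and significance
requires p < 0.05 *and* ≥ 10 voxels; the extent gate is applied at
reporting, not when forming the null, and is configurable.

Two numerical notes. First, sign flips leave per-voxel sums of squares
unchanged and label shuffles leave totals unchanged, so all permutation
t maps follow from one matrix multiply per batch — the permuted
statistics are algebraically identical to recomputing t from scratch
(the exhaustive sign-flip test verifies this against an enumeration
oracle that clusters with igraph). Second, the family-wise error
calibration in the acceptance suite runs with `min_size = 1`: under
pure-noise nulls at α = 0.005 on a 12³ grid, supra-threshold components
almost never reach 10 voxels, so with the extent gate active the
empirical rate would be near zero — valid but uninformative about the
Monte-Carlo p itself, which is what the calibration is meant to check.
The suite uses 200 null cohorts of 10 + 10 subjects at 500 permutations
(the acceptance script, 100 cohorts), sizes chosen to finish on one CPU
while leaving the binomial interval around 0.05 narrow enough to detect
miscalibration.

## Partial least squares correlation

Subject-level behaviour (item and pair Pr, n × 2) and neural measures
(mean distinctiveness per cluster, n × q) are column z-scored, their
between-person Pearson correlation matrix is decomposed by SVD, and the
first latent variable is tested by permuting the rows of one block
(10,000 permutations of the first singular value by default; permuting Y
or X rows is equivalent). Robustness comes from bootstrap resampling of
subjects (10,000 by default): each resample's first neural salience is
sign-aligned to the original by dot product (no Procrustes — only one
latent variable is interpreted), and the bootstrap ratio is the original
salience over the bootstrap SE (floored at 1e-12), with |BSR| > 1.96 as
the robustness criterion. The first behaviour salience is forced
non-negative to fix the SVD sign indeterminacy. "Between-person
correlation matrix" is read as correlation, not covariance, which makes
the z-scoring explicit and the 1 × 1 case reduce to |r|. Within-group
standardisation is exposed as a flag; bootstrap resampling is
unstratified by default with stratification available as an option.

## The synthetic cohort generator

The generator is the package's test surface, not a simulation of raw
BOLD physics. Per in-region voxel and trial,
`beta = √a_cat · C(category) + √b_item · I(item) + √(1 − a_cat − b_item) · ε`
with independent unit-variance Gaussian category patterns (one per
category), item patterns (one per stimulus, sampled once and reused in
TD2) and noise. Unit-variance components make expected Pearson
correlations equal shared-variance fractions — same category: `a_cat`;
same item across phases: `a_cat + b_item` — giving a closed-form test
surface (verified by direct simulation at 1e5 voxels, and by parameter
recovery at 5,000 voxels to ±0.03 after a `tanh(mean z)` back-transform,
where the atanh convexity bias is negligible at these voxel counts).
Out-of-region voxels are pure noise. An optional stability parameter
ρ mixes fresh item patterns into TD2 (`ρ·I + √(1−ρ²)·I′`) to emulate
reduced representational stability; the default ρ = 1 models perfectly
stable representations. Age groups differ only through their
`(a_cat, b_item)` fractions.

Memory outcomes are Bernoulli draws with
`logit p(hit) = β0 + β1_item · d_item + β1_cat · d_cat` on trial-wise
distinctiveness; pair judgments use `β0_pair + β1_cat · d_cat`, and new
objects are correctly rejected with fixed specificity 0.85 (only old-item
outcomes carry a generative model, so a single specificity is the
simplest closure for new items). Item outcomes are propagated to the encoding trials
of the same stimulus for subsequent-memory splits.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spatial autocorrelation and smoothness of
BOLD noise, scanner drift and motion artefacts, haemodynamic variability
across regions and subjects, non-Gaussian signal distributions,
hippocampal effects of the associative task, and any true
representational geometry beyond the two-level category/item structure.
Calibration results (e.g. the nominal family-wise error) therefore
validate the statistical machinery under exchangeability, not the
spatial null model of real fMRI.

## Two-stage association analyses

The reference analyses for trial-wise effects are random-slopes mixed
models (`Memory ~ Age × Distinctiveness + (1 + Distinctiveness |
Subject)` and `Item ~ Age × Category + (1 + Category | ID)`). The
package deliberately substitutes a two-stage summary-statistics
approach: per-subject slopes (logistic for binary memory, OLS for
continuous), then a one-sample t on the slopes for the main effect and a
two-sample t across age groups for the interaction. This is numerically
lighter, has no convergence failures at small trial counts, and is
unbiased for the population mean slope under the random-slopes model;
its cost is some efficiency relative to partial pooling.
Perfect-separation slopes are clipped at ±10 with a warning.
`export_long_table()` emits the subject/group/trial/distinctiveness/
outcome table so the exact mixed-model formulas can be fit in any
mixed-model tool. Pair memory is scored over all old-pair judgments by
default, with a flag to condition on a correct item response, since the
scoring convention for pairs after item misses varies between studies.

## Problem sizes and determinism

All simulations in the tests and the acceptance script are desk-scale by
design: 12³ (or smaller) grids, 20–40 trial designs, groups of 8–20
subjects, 200–500 permutations, chosen so the whole suite runs on one
CPU in minutes while keeping every statistical check at useful
resolution; the full study-scale design (320 objects, 100 subjects,
1,000+ permutations) is reached by passing `design_spec()` defaults and
larger group sizes to the same functions. Every stochastic stage takes
an explicit seed; subject-, permutation- and bootstrap-level seeds are
derived deterministically from a master seed, so a configuration
reproduces its report bit for bit (`run_pipeline()` is tested for
this). Volumes are written as float32 NIfTI; statistics are computed in
double precision.

## Known limitations

- The searchlight engine holds a centres × pair-chunk matrix in memory;
  full-brain grids with tens of thousands of pairs need the chunk size
  left at its default or lowered.
- The LSS approximation error with many overlapping distinct-amplitude
  trials is inherent to the estimator (see above).
- The two-stage analysis does not shrink extreme subject slopes; with
  very few trials per subject the interaction test is conservative.
- Cluster inference assumes exchangeability across subjects within
  group; covariate adjustment is out of scope.
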