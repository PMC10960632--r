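# patsim

Pattern similarity searchlight analysis of neural distinctiveness and its
age-related decline (neural dedifferentiation).

## The scientific problem

In older adults, stimulus-evoked fMRI activity patterns tend to be less
distinct than in younger adults, and this *neural dedifferentiation* has
been linked to poorer episodic memory. Distinctiveness can be measured at
two representational levels:

- **Item level** — how reliably a single stimulus evokes the same pattern
  across repeated presentations, relative to its similarity to other
  stimuli:

  `item_diff = mean_i z(r(TD1_i, TD2_i)) − mean_{i≠j} z(r(TD1_i, TD2_j))`

- **Category level** — how much more similar patterns are within a
  stimulus category (objects) than between categories (objects vs
  scenes), computed within the first scanning phase:

  `category_diff = mean z(r(object, object | different runs)) − mean z(r(object, scene))`

where `r` is the across-voxel Pearson correlation of two trial-wise beta
patterns and `z = atanh` is the Fisher transform. Both metrics are swept
across the brain in 4-mm spherical searchlights, producing per-subject
maps. Group contrasts (within group: dependent t; between age groups:
independent t) are thresholded at voxelwise p < 0.005 and assessed with
nonparametric **cluster-mass Monte-Carlo permutation tests** (cluster
statistic = sum of member t values; max-statistic null over condition
swaps or group-label shuffles; significant if Monte-Carlo p < 0.05 and
≥ 10 voxels). Subject-wise distinctiveness extracted from significant
clusters is related to recognition memory (item and pair Pr) with
**partial least squares correlation** (SVD of the behaviour × neural
correlation matrix, 10,000 permutations of the first singular value,
10,000 bootstrap resamples; |bootstrap ratio| > 1.96 marks a robust
neural contribution), and trial-wise distinctiveness is related to
memory outcomes with a two-stage per-subject slope analysis.

The package is aimed at researchers who want a tested, reproducible
implementation of this analysis chain — and a synthetic cohort generator
with *known* signal structure, so every stage can be validated without
scan data: per-voxel trial betas are drawn as

`beta = sqrt(a_cat)·C(category) + sqrt(b_item)·I(item) + sqrt(1 − a_cat − b_item)·ε`

with unit-variance Gaussian components, so the expected Pearson
correlation between same-category trials is `a_cat` and between
repetitions of the same item is `a_cat + b_item`. Age groups differ in
these variance fractions, and recognition outcomes are drawn from a
logistic model on trial-wise distinctiveness.

## Worked example

```r
library(patsim)

# a desk-scale cohort: 8 young + 8 old subjects, 12^3 grid, 40 objects,
# group a_cat/b_item 0.10 vs 0.05, memory driven by distinctiveness
cfg <- pipeline_config(seed = 7)
rep <- run_pipeline(cfg)

rep$age_clusters$n_significant_item
#> [1] 1
rep$age_clusters$item[rep$age_clusters$item$significant, ]
#>   size     mass sign peak_x peak_y peak_z        p_mc significant
#> 2   26 111.7967    1      7      6      7 0.004975124        TRUE
rep$behavior$chance
#> [1] 0.3125
unlist(rep$trialwise_association)
#>  mean_slope      t_main      p_main     t_group     p_group
#>  1.73440661  2.33495892  0.03385286 -1.19373897  0.25241610
```

The significant positive (young > old) item-level cluster of 26 voxels
peaks at (7, 6, 7) — inside the generator's central signal block: the
pipeline recovers the planted age difference at its Monte-Carlo floor
(p = 1/201 at 200 permutations). `rep$behavior$chance` is the analytical
chance level of item recognition, `p(old response) × n_old / n_total`;
the demonstration design's 30/48 ratio equals the full design's 250/400,
so both give 0.3125, conventionally printed as 0.31. The trial-wise
association block reports the two-stage distinctiveness–memory analysis:
a positive mean within-subject slope (p = 0.034) and no age-by-slope
interaction at this cohort size.

Lower-level entry points: `generate_design()`, `generate_betas()`,
`fit_trial_betas()` (LSS GLM), `item_distinctiveness()`,
`category_distinctiveness()`, `cluster_permutation_test()`,
`plsc_analysis()`, `memory_scores()`, `twostage_association()`.

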