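---
title: "Gradient-forest turnover functions and seed-zone delineation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-forest turnover functions and seed-zone delineation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gfzone)
```

This vignette is the package's account of its science: the model each stage
implements, the assumptions behind it, the parameters that matter, the
numerical choices made where the method leaves room, and what the synthetic
validation does and does not establish.

## 1. Per-SNP forests and the retention screen

The unit model is a regression forest for one locus: individual-level diploid
dosages (0/1/2) regressed on 20 annual climate variables with 200 bootstrap
CART trees. Dosages, not population allele frequencies, are the response, so
within-population binomial sampling noise is part of the residual and the
forest's explainable variance is bounded by the true climate-associated
fraction of dosage variance.

Model fit is out-of-bag: `R² = 1 − MSE_oob / Var(y)`, which may be negative.
Only SNPs with strictly positive OOB R² are retained ("predictive" SNPs);
everything downstream — importances, densities, turnover — is built from the
retained set. Two guards keep R² well defined at degenerate settings:
samples never out-of-bag are excluded from `MSE_oob`, and a fit whose OOB
coverage falls below 50% of samples (possible at very small tree counts) is
flagged and screened out rather than scored. Monomorphic loci and loci with
fewer than 30 complete cases are skipped with a log entry; missing calls are
otherwise handled by fitting each locus on its complete cases — no
imputation, so no imputation model can leak climate signal into the
response.

Forest hyperparameters (all recorded in the fitted object): `n_trees = 200`;
`mtry = floor(p/3) = 6` predictors tried per split, the regression-forest
convention; minimum child size 5; bootstrap size `n` with replacement. The
forest RNG is a seeded Mersenne Twister in compiled code, so fits are
bit-reproducible across platforms and independent of R's RNG state.

## 2. Split importance, densities, and turnover functions

Every split is an event `(predictor, value, impurity reduction)`, with
impurity measured as the reduction in residual sum of squares. The method's
central accounting identity is an exact R² partition: for a retained SNP,
its OOB R² is divided across predictors proportionally to the summed split
reductions, so predictor shares of one SNP sum to its R² (relative tolerance
1e-9, tested), and a predictor's **overall importance** is the mean share
over retained SNPs.

Along each predictor the package bins split reductions into 101 equal-width
bins over the observed range (`I(x)`, each SNP pre-scaled to its R² share),
bins the observed predictor values into a density integrating to one
(`d(x)`), and standardizes `f(x) = I(x)/d(x)`. Bins where `d` falls below 1%
of its maximum use that floor as denominator and are flagged; without the
floor, a handful of splits landing in a climate range the sample barely
covers would dominate `f`. The reference implementation's kernel/whisker
density scheme is not published at this granularity, so the binned estimator
is this package's declared choice; the bin count is configurable and the
turnover totals are invariant to it by construction, because each aggregate
**turnover function** — the cumulative integral of `f` — is rescaled so its
right-endpoint total equals the predictor's overall importance. Turnover
functions are monotone non-decreasing from zero, evaluate to 0 below the
training range and to the total above it, and are interpolated linearly
between breakpoints (a staircase mode exists and is what the exhaustive
split-tally oracle tests compare against, exactly, on forests small enough
to enumerate).

## 3. From climate grids to genomic surfaces

Evaluating the 20 turnover functions at a raster cell's climate yields its
position in genomic-composition space; cells with similar vectors are
predicted to host similarly adapted genotypes. The transformation is
monotone band-wise by construction. PCA then summarizes the surface:

* fitted on **all masked-in cells** (the surface being the object of
  interest), with a flag to restrict to sample sites for sensitivity checks;
* **centered but not variance-scaled** — bands share the
  cumulative-importance scale and rescaling would erase exactly the
  importance weighting that makes dominant predictors dominate the map;
* signs fixed deterministically (largest-magnitude loading of each component
  made positive) so maps reproduce across runs and platforms.

The top three scores drive the RGB map (default stretch: 2nd–98th
percentile, parameters recorded on the object) and the clustering space.

## 4. Zonation

Partitioning around medoids (BUILD + SWAP, Euclidean distance on the top-3
PC scores) is run for k = 2..16. Because BUILD + SWAP is deterministic, the
"restart" budget is spent on seeded random initializations refined by SWAP,
keeping the best solution; each k is additionally warm-started from the
k−1 medoids plus the point farthest from them, which guarantees the
within-cluster-variation curve W(k) is non-increasing (adding a medoid
cannot raise the cost, SWAP only lowers it). PAM being quadratic, grids
beyond 20 000 cells are clustered on a seeded subsample and all cells
assigned to the nearest medoid (ties to the lowest zone id).

W(k) is reported scale-free: mean distance to the assigned medoid divided by
the RMS distance of all points to the global 1-medoid center. The absolute
magnitudes therefore depend on this normalization choice (the quantity has
no canonical units), but the shape of the curve — what the elbow rule
consumes — does not.

The number of zones is the smallest k whose next reduction is
"substantially less" than the typical prior reduction:
`r(k+1) < θ · median(r(2..k))` with θ = 0.5 by default. The scan always
includes k = 1 internally so `r(2) = W(1) − W(2)` is defined. θ is exposed
and the full decision trace is returned, because "substantially less" is a
judgment call: on smooth, cluster-free surfaces the rule triggers early (a
two-zone cut of a single dominant gradient is a faithful answer, not a
failure), on geometric-decay profiles it can trigger late, and when it never
triggers the maximum k is returned with an explicit no-elbow flag.

Zone ids are relabeled 1..k by descending area for stable presentation — a
pure permutation, tested as such. Overlap validation counts co-registered
cells: rate = 100 × overlap area / denominator area, with the reference
zone's area as the default denominator and `gf`/`union` conventions
available, since the wording of published overlap rates rarely pins the
denominator down. Many-to-one zone correspondences compare label sets. The
averaged rate is area-weighted by default with a simple-mean option, for the
same reason. Backward comparison re-cuts the scanned clustering at a
reference map's k.

## 5. The synthetic landscape: what it emulates, what it does not

The generator provides known ground truth under one seeded RNG in a fixed
call order (bit-reproducible):

* **Climate**: 20 bands on a grid, each latent field an FFT-smoothed
  Gaussian random field (squared-exponential kernel, correlation length 12
  cells by default) blended 50/50 in variance with a planar trend of random
  orientation. Latent fields are orthonormalized before being colored by the
  inter-variable correlation matrix, so realized cross-band correlations
  equal the configured matrix exactly; the default matrix is a two-factor
  (temperature/moisture) structure, within-group loading √0.6, factor
  correlation 0.3, with physically sensible signs (DD<0 and CMD run against
  MAT and MAP respectively). Bands are affinely rescaled into plausible
  British-Columbia/Alberta ranges; MAT spans −7.3..10.3 °C and MAP
  225..8769 mm, the envelope of productive lodgepole-pine climate in the
  region, with the other 18 ranges chosen once as realistic values.
* **Sampling**: population cells drawn without replacement; individuals
  split as evenly as possible; every individual inherits its cell's exact
  climate row.
* **Adaptive SNPs**: dosage ~ Binomial(2, plogis(a + b·z)) with z the
  standardized driver variable; defaults a ∈ [−1, 1], |b| ∈ [1.5, 3] with
  random sign — strong but not deterministic clines.
* **Neutral SNPs**: Balding–Nichols — ancestral frequency π ~ U(0.1, 0.9),
  population frequency ~ Beta(π(1−F)/F, (1−π)(1−F)/F), dosages binomial —
  the minimal one-parameter model of hierarchical differentiation; F = 0.1
  by default. An optional flag adds the same population deviation to
  adaptive SNPs to study structure/adaptation confounding.

Default sizes are the desk-scale study conditions used across the test
suite and the acceptance script: 50 populations × 20 individuals, 200
adaptive + 2000 neutral SNPs, a 60 × 60 grid of 800 m cells.

Deliberately not emulated: linkage disequilibrium (loci independent),
coalescent/recombination history, genotyping error and missing-data
patterns, isolation-by-distance spatial autocorrelation of the neutral
structure (population effects are exchangeable across populations), and
climate-surface error. Passing tests on this generator therefore establish
the correctness of the estimators and accounting, not robustness to those
real-data features.

## 6. A known limitation: positive-R² screening under strong structure

The retention screen is advertised as a filter against neutral structure,
and on unstructured nulls it is: permuted dosages average OOB R² ≈ 0 and
essentially zero retention. But a neutral locus under *strong* population
structure is genuinely predictable from climate whenever climate
fingerprints the populations — with 50 populations, 20 climate dimensions
and all individuals of a population sharing one climate row, a forest can
memorize the population → frequency map out-of-bag. At F = 0.1 the
between-population variance fraction (≈ F) sits well above the forest's
overfitting penalty, so neutral retention approaches 100% and the
adaptive/neutral retention contrast collapses to ≈ 1. The sharp empirical
contrasts reported for real conifer data correspond to far weaker intergenic
differentiation (FST on the order of 0.01, consistent with retained-neutral
R² around 1%): there the structure signal is below the screen's noise floor.
Users applying the package where FST is substantial should not read the
positive-R² screen as structure control; pairing it with an upstream
candidate scan (the candidate-set workflow the package's set-assembly tools
support) is the appropriate design.

## 7. Numerical choices and degenerate inputs

* MAF filter: strict `> 0.05`, pooled over all individuals; idempotent;
  per-SNP missingness above 20% drops the locus.
* Conservation checks at relative 1e-9; monotonicity enforced up to 1e-12
  numeric dust, then clipped.
* Zero retained SNPs is a valid empty model (zero importances, flat
  turnover), not an exception.
* A predictor never split on has an all-zero density and a flat turnover.
* Constant score bands map to mid-gray in the RGB stretch, with a warning.
* Nearest-medoid ties break to the lowest zone id; importance-ranking ties
  break alphabetically (C-locale radix order).
* Equal-area accounting requires both maps on one projected grid; maps on
  different cell sizes are refused rather than silently resampled.

## 8. Validation problem sizes

The test suite exercises forests at n = 40–1000 samples, gradient forests up
to 2200 loci × 200 trees, exhaustive-oracle clustering instances up to 14
points, scans to k = 16 on up to a few thousand cells, and end-to-end
pipeline runs on 12 × 12 to 60 × 60 grids — sizes chosen so the full suite
re-derives every accounting identity and oracle comparison in minutes on a
single core, while the same code paths scale to array-scale SNP sets (the
forest core is compiled, and aggregation is streaming: per-SNP split lists
are binned as they are produced rather than stored).
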