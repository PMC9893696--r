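---
title: "Grey-matter structural covariance networks: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-matter structural covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Grey-matter (GM) volumes of anatomically or functionally related regions
covary across individuals: a person with a thicker hippocampus tends to
have thicker medial temporal and default-network cortex too. In prodromal
cognitive decline this *structural covariance* — the synchrony of
inter-individual anatomical variation — weakens before frank regional
atrophy is measurable, which makes covariance-derived summaries candidate
predictors of whether a cognitively normal elder will progress to mild
cognitive impairment (MCI), or an MCI patient will revert to normal.

`scnet` implements that analysis end to end:

1. **Seed-PLS network construction.** For a network anchored by seed
   coordinates (default, frontoparietal, and hippocampal networks, each with
   two stereotaxic seeds), the participants-by-seeds matrix of mean
   in-sphere GM density is correlated, across participants, with every
   other voxel of the brain mask. The seeds-by-voxels correlation matrix
   `R` is decomposed by SVD, `R = U D V'`; each latent variable (LV) pairs
   a seed-salience vector (column of `U`) with a whole-brain voxel-salience
   pattern (column of `V`), with the singular value measuring explained
   cross-block covariance. Only LV1 is carried forward.
2. **Inference.** LV significance comes from permutation: participant rows
   of the seed matrix are shuffled against the voxel block (1000 draws) and
   the singular value recomputed; `p = (1 + #{permuted >= observed}) /
   (N + 1)`. Voxel reliability comes from a participant-level bootstrap
   (1000 draws with replacement): each voxel's bootstrap ratio (BSR) is its
   weight divided by the bootstrap standard error of that weight.
3. **Thresholding and scores.** The top 3% of analysis voxels by |BSR|
   form the network's sparse weight map (weights = LV1 voxel saliences).
   An individual's *score map* is density times weight on that support, and
   the *composite score* — the sum — indexes the structural integrity of
   the network for that person.
4. **Group comparison.** Composite scores are compared between groups
   (stable vs progressing normals; non-reverting vs reverting MCI) by
   ANCOVA controlling age, sex, education, and total intracranial volume.
5. **Prediction.** Fivefold-stratified cross-validated random forests (500
   trees, sqrt(p) features per split) classify future transition from the
   baseline score-map voxels; performance is the mean and SD of per-fold
   ROC AUC, with sensitivity/specificity at the Youden-optimal point of
   the pooled out-of-fold curve, and impurity importances (averaged over
   folds, normalised to sum 1) are mapped back to voxels and atlas regions.

## The synthetic cohort generator

Real scans for the motivating cohorts are not redistributable, so every
stage is validated on synthetic cohorts with known ground truth. The
generator emulates smoothed voxel-based-morphometry GM maps with a
single-factor covariance structure. For participant $i$ in group $g$,
voxel $j$ of blob $b$:

$$x_{ij} = \beta_0 + s\,[\,a_g \lambda\, g_{ib} + \delta_g + c_i + \varepsilon_{ij}\,],
\qquad g_{ib} = \sqrt{\rho_g} f_i + \sqrt{1-\rho_g}\, h_{ib},$$

with shared anatomical factor $f_i \sim N(0,1)$, blob-private factors
$h_{ib}$, loading $\lambda$ (scaled per group by $a_g$), synchrony
$\rho_g \in (0,1]$, group atrophy offset $\delta_g$, covariate term
$c_i$ (age and TIV slopes), and i.i.d. noise
$\varepsilon_{ij} \sim N(0,\sigma)$. Background voxels carry only
$\beta_0 + s(c_i + \varepsilon_{ij})$. The volume is then Gaussian-smoothed
(8 mm FWHM at 4 mm voxels by default) and clamped to [0,1].

Design choices worth spelling out:

- **Signal units and `signal_scale`.** $\lambda$, $\sigma$, $\delta$ are
  dimensionless; `signal_scale` ($s$ = 0.12 density units) places the
  signal inside [0,1] with negligible clamping (≈2 per 10,000 tail mass at
  the canonical $\lambda = 1$, $\sigma = 0.5$). Every statistic downstream
  — correlations, saliences, BSR, F, AUC — is invariant to this positive
  scaling, so it is a display calibration, not a tuning knob. Taking
  $\lambda = 1$ directly in density units would clamp roughly a third of
  signal-voxel values and destroy the factor model's closed-form
  covariance.
- **Geometry.** Network voxels (3% of the grid) are grown as compact blobs
  around *all* centres — each seed sphere acquires a surrounding annulus,
  plus distal blobs — because covariance networks invariably include the
  seed's own extended region. Compact blobs survive smoothing; scattered
  voxels would not.
- **Group defaults.** $\delta = (0, -0.7, -1.0, -0.2)$ and loading scales
  $(1, 0.85, 0.7, 1.0)$ for sNC/pNC/non-rMCI/rMCI, with 28/18/20/24
  analysis participants and 65 template sNC. With $\lambda = 1$ the
  composite-score effect sizes are then Cohen's d ≈ 0.7 (sNC vs pNC) and
  ≈ 0.8 (non-rMCI vs rMCI), the range that published progression/reversion
  cohorts of this size report; reverting MCI retains covariance strength
  while non-reverting MCI loses both density and synchrony.
- **What it does not emulate.** Cortical anatomy and topology, longitudinal
  change, scanner/site effects, non-Gaussian atrophy, registration error.
  Passing tests demonstrate the statistical machinery is correct and
  calibrated under the factor model, not that real cohorts will show the
  same effect sizes.

## Calibration experiments and their design rationale

`R/experiments.R` pins the exact conditions used by the tests, the
analysis scripts and `scripts/acceptance.R`:

- **Permutation calibration** (200 cohorts, n = 40, 200 permutations).
  The null cohort removes *every* source of seed-voxel association: the
  factor ($\lambda = 0$), group effects, the global age/TIV gradients (a
  global gradient correlates every voxel with the seed — a true
  association), and smoothing (smoothed noise correlates the seed's
  spatial neighbourhood with the seed mean — also a true association).
  What remains is i.i.d. noise, the exchangeable null the permutation test
  actually assumes; rejection at $\alpha = 0.05$ then sits at the nominal
  10/201 ≈ 0.0498 and the p-values are uniform. Relatedly, the PLS voxel
  block always excludes the seed-sphere voxels themselves ("the seed and
  the *other* voxels of the brain"): a seed trivially correlates with its
  own members.
- **Bootstrap ratios on the projection scale.** The BSR denominator is the
  bootstrap SD of the *unnormalised* cross-block projection
  $R'u$ (salience times singular value), not of the unit-norm salience.
  The unit-norm constraint couples every reliable voxel to the resampling
  jitter of the whole-brain norm (their bootstrap draws correlate at 1.00),
  flooring BSR near $1/\mathrm{cv}(\lVert R \rVert) \approx 40$ for every
  reliable voxel and erasing the ranking the top-3% threshold depends on.
  On the projection scale, planted-network recovery by the top-3%
  threshold is ≈ 0.90-0.99 at the canonical conditions
  ($\lambda = 1$, $\sigma = 0.5$, n = 60) while pure-noise voxels sit at
  |BSR| ≈ 2.5.
- **Prediction power** uses a cohort with a one-noise-sd atrophy shift
  ($\delta = 0.5 = 1.0\sigma$) and loading $\lambda = 0.25$. The loading
  matters: the shared factor is common to every retained voxel, so it acts
  as irreducible noise for a mean-shift classification. At $\lambda = 1$
  the Bayes-optimal AUC for this contrast is ≈ 0.64 *for any classifier*;
  at $\lambda = 0.25$ the composite-level effect size is Cohen's d ≈ 2
  and a well-implemented classifier should reach AUC ≥ 0.85. We fix
  $\lambda = 0.25$ from that analysis, not from tuning.
- **Mechanism contrast.** The claim that synchrony loss precedes regional
  atrophy is restated as a generator property: two groups with *identical
  marginal distributions at every voxel* (no mean shift, equal total
  loading) differ only in $\rho_g$ (1 vs 0.2). A single region's mean
  density then carries no group information at all (AUC ≈ 0.5), while
  multi-voxel score maps detect the decoupling of blobs (AUC ≈ 0.95+).
  A group-wise loading-scale difference would instead change marginal
  variances, letting even a single region discriminate and making the
  score-map advantage depend on noise constants; the synchrony
  parameterisation isolates the mechanism cleanly.

## Numerical and procedural choices

- Voxel indices are 0-based against the NIfTI affine; nearest-voxel
  rounding breaks half-way ties toward negative infinity.
- Analysis mask: mean density > 0.2 across participants (the usual VBM
  convention; configurable) and cross-participant variance > 0 so Pearson
  correlation is always defined.
- Seed spheres default to 6 mm radius — the seed extent around published
  coordinates is not standardised, and this is the largest unstated
  parameter of the method; it is exposed in `seed_spec()`.
- SVD of the short-and-wide correlation matrix goes through the 2x2 Gram
  matrix; LV sign is fixed so voxel saliences sum to a non-negative value;
  bootstrap LVs are sign-aligned to the original by the dot product of
  voxel saliences (with ≤ 2 seeds a full Procrustes rotation is
  unnecessary).
- Thresholding retains `ceiling(0.03 * n_voxels)` voxels by |BSR|, ties
  broken by ascending voxel index; a `signed` option restricts to
  positive-BSR voxels; weights default to LV salience with a `bsr` option.
- p-values use the (k+1)/(N+1) estimator, so p = 0 cannot occur.
- The ANCOVA group test is the partial F of the group term; raw and
  covariate-adjusted means (at pooled covariate means) are both reported,
  since group means ± SD are conventionally reported raw.
- AUC is the Mann-Whitney probability with ties counted one half; the
  reported operating point maximises Youden's J on the pooled out-of-fold
  curve (a fixed 0.5 cutoff is meaningless for imbalanced groups).
- Forest defaults: 500 trees, unlimited depth, sqrt(p) features per split,
  stratified folds, impurity importance (deterministic given the seed);
  permutation importance is available via `importance = "permutation"`.
- Every stochastic routine takes an integer seed and is bit-reproducible;
  the pipeline manifest records per-file checksums.

## Problem sizes

The bundled experiments run on a 24x24x24 grid at 4 mm (13,824 voxels,
≈ 415 network voxels), with cohorts of 40-200 participants, 1000
permutations and 1000 bootstraps for network building, and 200-cohort /
100-repeat calibration loops. A full run of the analysis scripts or the
acceptance script completes in minutes on one CPU; all sizes scale up via
`sim_config()`.

## Known limitations

- Only LV1 is modelled; secondary covariance patterns are out of scope.
- The generator's single-factor structure cannot produce overlapping
  networks or graded covariance hierarchies.
- ANCOVA assumes homogeneous covariate slopes across groups.
- With two seeds the PLS cannot distinguish seed-specific contributions;
  seed saliences are reported but not tested individually.
- Real-data preprocessing (segmentation, normalisation, smoothing, QA) is
  assumed done upstream; maps must already share one grid.
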