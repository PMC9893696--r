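# scnet — grey-matter structural covariance networks

`scnet` builds **structural covariance networks** from voxel-wise
grey-matter (GM) density maps, scores individuals against them, and uses
those scores to predict future cognitive transition — progression from
normal cognition to mild cognitive impairment (MCI) and reversion from MCI
back to normal. It is aimed at neuroimaging researchers working with
voxel-based-morphometry output (preprocessed, spatially normalised,
smoothed GM density maps in NIfTI).

## The method

Inter-individual differences in regional GM covary across anatomically
related regions; this synchrony weakens in prodromal neurodegeneration.
The pipeline quantifies it by **seed-based partial least squares**:

1. For a network anchored by seed coordinates (default-mode,
   frontoparietal, and hippocampal networks are built in via
   `network_seeds()`), compute the participants × seeds matrix *S* of mean
   in-sphere GM density, and the between-participant Pearson correlation
   *R* (seeds × voxels) between *S* and every other voxel in the brain
   mask.
2. Decompose *R = U D Vᵀ*. Latent variable 1 pairs a seed salience
   (*u₁*) with a whole-brain voxel salience pattern (*v₁*); its singular
   value *d₁* measures explained cross-block covariance. Significance is
   assessed by 1000 row permutations, *p = (1 + #{d₁* ≥ d₁}) / (N + 1)*.
3. A 1000-draw participant bootstrap yields each voxel's **bootstrap
   ratio** (BSR) — its weight divided by the weight's bootstrap standard
   error. The top 3% of voxels by |BSR| form the network's weight map.
4. An individual's **score map** is density × weight on that support; the
   **composite score** (their sum) indexes that person's network
   integrity. Composite scores are compared between clinical groups by
   ANCOVA (controlling age, sex, education, total intracranial volume).
5. Fivefold-stratified cross-validated **random forests** (500 trees) on
   the score-map voxels predict the transition label; performance is
   per-fold ROC AUC (mean ± SD), with sensitivity/specificity at the
   Youden point of the pooled out-of-fold curve, and feature importances
   mapped back to voxels and atlas regions.

Because the motivating cohorts' raw MRI cannot be redistributed, the
package ships a synthetic-cohort generator (`sim_config()`,
`generate_cohort()`) that plants a known seed-linked covariance network in
smooth GM-like maps — with group-dependent atrophy, covariance loading,
synchrony, and age/TIV covariate effects — so every stage is testable
against ground truth. See the vignette
(`vignettes/structural-covariance-networks.Rmd`) for the generative model
and all design decisions.

## Worked example

Build a network on a 65-participant template, score an independent
analysis cohort (28 sNC / 18 pNC / 20 non-rMCI / 24 rMCI), compare groups,
and predict MCI reversion:

```r
library(scnet)

tcfg  <- sim_config(n_per_group = c(sNC = 65L), rng_seed = 5102L)
tmpl  <- generate_cohort(tcfg)
model <- build_network(tmpl$maps, sim_seed_spec(tcfg), make_mask(tmpl$maps),
                       n_permutations = 1000, n_bootstraps = 1000,
                       rng_seed = 5103L)
model
#> <scn_model> custom network | 13786 masked voxels | 414 retained | LV1 perm p = 0.002997

ana    <- generate_cohort(sim_config(rng_seed = 5104L))
scored <- score_cohort(ana$maps, model)
ancova_compare(scored$scores$composite_score, ana$cohort,
               c("non-rMCI", "rMCI"))
#> <scn_ancova> non-rMCI vs rMCI: F(1, 38) = 30.855, p = 2.323e-06

lab  <- transition_labels(ana$cohort, c("non-rMCI", "rMCI"))
rows <- attr(lab, "rows")
ft   <- build_features_from_scores(
          list(scores = scored$scores[rows, ],
               score_matrix = scored$score_matrix[rows, , drop = FALSE]),
          model, labels = lab)
cross_validated_rf(ft, n_folds = 5, n_trees = 500, rng_seed = 5105L)
#> <prediction_report> AUC 0.858 (+/- 0.154) over 5 folds | SEN 0.875 SPE 0.750
```

The network is highly significant under permutation, recovers 99% of the
planted covariance voxels, the reverting-MCI group shows the higher
composite score after covariate adjustment (the planted ordering), and the
score-map forest separates reverters from non-reverters well above chance.

`analysis/01_simulate.R` … `analysis/05_calibration.R` run the same
workflow as a scripted narrative (simulate → build → score/compare →
predict → calibrate), writing tables under `results/`.

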