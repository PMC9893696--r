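#' Calibration and validation experiments
#'
#' These functions pin down the synthetic study conditions used to validate
#' each stage of the pipeline, so that tests, the acceptance script and the
#' analysis scripts all run the identical experiment. All of them zero the
#' global age/TIV covariate gradients: a global gradient is itself a true
#' seed-voxel association, so it belongs in the covariate-adjustment
#' experiments (ANCOVA), not in the covariance-mechanism calibrations.
#'
#' @name experiments
NULL

#' Planted-network configuration (canonical covariance conditions)
#'
#' One-group cohort with the canonical planted-covariance conditions:
#' factor loading 1, voxel noise sd 0.5 (signal units), network fraction
#' 0.03, default grid and smoothing.
#'
#' @param n participants (default 60).
#' @param rng_seed integer seed.
#' @param lambda,noise_sd override the canonical signal-to-noise.
#' @export
planted_config <- function(n = 60, rng_seed = 0, lambda = 1, noise_sd = 0.5) {
  sim_config(n_per_group = c(sNC = as.integer(n)),
             lambda = lambda, noise_sd = noise_sd,
             covariate_effects = list(age_slope = 0, tiv_slope = 0),
             rng_seed = rng_seed)
}

#' Network recovery experiment
#'
#' Generates a planted cohort, builds the covariance network end-to-end
#' (permutation + bootstrap + top-fraction threshold) and measures how much
#' of the planted network the retained voxel set recovers.
#'
#' @param rng_seed integer seed.
#' @param n cohort size (default 60).
#' @param n_permutations,n_bootstraps resampling sizes (default 1000).
#' @return list: \code{recovery} (fraction of planted network voxels
#'   retained), \code{perm_p} (LV1 permutation p), \code{model},
#'   \code{truth}.
#' @export
recovery_experiment <- function(rng_seed = 0, n = 60,
                                n_permutations = 1000, n_bootstraps = 1000) {
  cfg <- planted_config(n = n, rng_seed = rng_seed)
  coh <- generate_cohort(cfg)
  mask <- make_mask(coh$maps)
  model <- build_network(coh$maps, sim_seed_spec(cfg), mask,
                         n_permutations = n_permutations,
                         n_bootstraps = n_bootstraps,
                         rng_seed = rng_seed + 1)
  list(recovery = mean(coh$truth$network_voxel_indices %in%
                         model$weight_map$voxel_index),
       perm_p = model$lv$perm_p,
       model = model, truth = coh$truth)
}

#' Permutation-test calibration on null cohorts
#'
#' Generates \code{n_cohorts} structureless cohorts and collects the LV1
#' permutation p-value of each; under the null these should be uniform and
#' reject at close to the nominal rate.
#'
#' @param rng_seed integer seed.
#' @param n_cohorts number of null cohorts (default 200).
#' @param n participants per cohort (default 40).
#' @param n_permutations permutations per cohort (default 200).
#' @param alpha nominal level for the rejection rate (0.05).
#' @return list: \code{p_values}, \code{rejection_rate}, \code{ks_p}
#'   (Kolmogorov-Smirnov uniformity p).
#' @export
null_calibration_experiment <- function(rng_seed = 0, n_cohorts = 200,
                                        n = 40, n_permutations = 200,
                                        alpha = 0.05) {
  p <- vapply(seq_len(n_cohorts), function(i) {
    cfg <- planted_config(n = n, rng_seed = rng_seed + i)
    coh <- generate_null_cohort(cfg)
    mask <- make_mask(coh$maps)
    pt <- permutation_test(coh$maps, sim_seed_spec(cfg), mask,
                           n_permutations = n_permutations,
                           rng_seed = rng_seed + 100000L + i)
    pt$perm_p[1]
  }, numeric(1))
  # p-values live on the discrete (k+1)/(N+1) grid, so ties across cohorts
  # are expected; the KS distortion from 201 support points is negligible
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(p_values = p, rejection_rate = mean(p <= alpha), ks_p = ks$p.value)
}

#' Atrophy-driven prediction cohort (focal mean shift)
#'
#' Two-group cohort whose groups differ by a planted mean density shift of
#' one noise sd on the network voxels, with modest covariance dispersion
#' (factor loading 0.25): a cohort whose focal atrophy dominates the shared
#' anatomical factor, mirroring strong regional atrophy in progressors. The
#' loading is set so the composite-score effect size is about Cohen's d = 2;
#' with a loading of 1 the shared factor alone would cap any classifier near
#' AUC 0.64 regardless of features.
#'
#' @param rng_seed integer seed.
#' @param n_per_group participants per group (default 60).
#' @export
atrophy_config <- function(rng_seed = 0, n_per_group = 60) {
  sim_config(n_per_group = c(`non-rMCI` = as.integer(n_per_group),
                             rMCI = as.integer(n_per_group)),
             lambda = 0.25, noise_sd = 0.5,
             group_mean_shift = c(sNC = 0, pNC = 0,
                                  `non-rMCI` = -0.5, rMCI = 0),
             group_loading_scale = c(sNC = 1, pNC = 1,
                                     `non-rMCI` = 1, rMCI = 1),
             covariate_effects = list(age_slope = 0, tiv_slope = 0),
             rng_seed = rng_seed)
}

#' Random-forest prediction experiment on an atrophy cohort
#'
#' Builds a network on a disjoint template, scores the analysis cohort, and
#' cross-validates a random forest on the score-map features. With
#' \code{permute_labels = TRUE} the labels are shuffled first (null
#' calibration of the classifier).
#'
#' @param rng_seed integer seed.
#' @param n_per_group per-group size (default 60).
#' @param n_template template cohort size (default 65).
#' @param n_permutations,n_bootstraps model-building resampling sizes.
#' @param permute_labels shuffle labels before cross-validation.
#' @param model optional pre-built \code{scn_model} (skips template/build).
#' @return the \code{prediction_report}, plus the \code{model} used.
#' @export
prediction_experiment <- function(rng_seed = 0, n_per_group = 60,
                                  n_template = 65,
                                  n_permutations = 500, n_bootstraps = 500,
                                  permute_labels = FALSE, model = NULL) {
  if (is.null(model)) {
    tcfg <- planted_config(n = n_template, rng_seed = rng_seed + 1,
                           lambda = 0.25)
    tmpl <- generate_cohort(tcfg)
    model <- build_network(tmpl$maps, sim_seed_spec(tcfg),
                           make_mask(tmpl$maps),
                           n_permutations = n_permutations,
                           n_bootstraps = n_bootstraps,
                           rng_seed = rng_seed + 2)
  }
  acfg <- atrophy_config(rng_seed = rng_seed + 3, n_per_group = n_per_group)
  ana <- generate_cohort(acfg)
  scored <- score_cohort(ana$maps, model)
  lab <- transition_labels(ana$cohort, c("non-rMCI", "rMCI"))
  if (permute_labels) {
    set.seed(rng_seed + 4)
    lab <- structure(sample(lab), rows = attr(lab, "rows"))
  }
  ft <- build_features_from_scores(scored, model, labels = lab)
  rep_ <- cross_validated_rf(ft, n_folds = 5, n_trees = 500,
                             rng_seed = rng_seed + 5)
  rep_$model <- model
  rep_
}

#' Null calibration of the cross-validated classifier
#'
#' Scores one atrophy cohort under a template-built model, then repeatedly
#' permutes the transition labels and re-runs the full stratified
#' cross-validation; the mean cross-validated AUC over repeats should sit at
#' chance.
#'
#' @param rng_seed integer seed.
#' @param n_repeats label permutations (default 100).
#' @param n_per_group per-group size (default 60).
#' @param n_permutations,n_bootstraps model-building resampling sizes.
#' @return list: \code{auc} (per repeat), \code{mean_auc}.
#' @export
prediction_null_calibration <- function(rng_seed = 0, n_repeats = 100,
                                        n_per_group = 60,
                                        n_permutations = 500,
                                        n_bootstraps = 500) {
  tcfg <- planted_config(n = 65, rng_seed = rng_seed + 1, lambda = 0.25)
  tmpl <- generate_cohort(tcfg)
  model <- build_network(tmpl$maps, sim_seed_spec(tcfg),
                         make_mask(tmpl$maps),
                         n_permutations = n_permutations,
                         n_bootstraps = n_bootstraps,
                         rng_seed = rng_seed + 2)
  acfg <- atrophy_config(rng_seed = rng_seed + 3, n_per_group = n_per_group)
  ana <- generate_cohort(acfg)
  scored <- score_cohort(ana$maps, model)
  lab <- transition_labels(ana$cohort, c("non-rMCI", "rMCI"))
  auc <- vapply(seq_len(n_repeats), function(r) {
    set.seed(rng_seed + 10000L + r)
    plab <- structure(sample(lab), rows = attr(lab, "rows"))
    ft <- build_features_from_scores(scored, model, labels = plab)
    cross_validated_rf(ft, n_folds = 5, n_trees = 500,
                       rng_seed = rng_seed + 20000L + r)$auc_mean
  }, numeric(1))
  list(auc = auc, mean_auc = mean(auc))
}

#' Synchrony-loss mechanism experiment
#'
#' The two groups have identical voxel-wise marginal distributions (no mean
#' shift, equal loading) but differ in how much of the anatomical factor is
#' shared across blobs: the non-reverting group is desynchronised
#' (\code{group_sync} 0.2 vs 1). A single-region mean density then carries
#' no group information, while multi-voxel covariance-network score maps
#' detect the lost synchrony — the desk-scale analogue of synchronous
#' atrophy change preceding single-region atrophy.
#'
#' @param rng_seed integer seed.
#' @param n_per_group per-group size (default 100).
#' @param n_template template size (default 65).
#' @param n_permutations,n_bootstraps model-building resampling sizes.
#' @return list: \code{auc_scores} (score-map features),
#'   \code{auc_region} (seed-region mean density), \code{auc_gap}.
#' @export
mechanism_experiment <- function(rng_seed = 0, n_per_group = 100,
                                 n_template = 65,
                                 n_permutations = 500, n_bootstraps = 500) {
  tcfg <- planted_config(n = n_template, rng_seed = rng_seed + 1)
  tmpl <- generate_cohort(tcfg)
  model <- build_network(tmpl$maps, sim_seed_spec(tcfg),
                         make_mask(tmpl$maps),
                         n_permutations = n_permutations,
                         n_bootstraps = n_bootstraps,
                         rng_seed = rng_seed + 2)
  acfg <- sim_config(
    n_per_group = c(`non-rMCI` = as.integer(n_per_group),
                    rMCI = as.integer(n_per_group)),
    lambda = 1, noise_sd = 0.5,
    group_mean_shift = c(sNC = 0, pNC = 0, `non-rMCI` = 0, rMCI = 0),
    group_loading_scale = c(sNC = 1, pNC = 1, `non-rMCI` = 1, rMCI = 1),
    group_sync = c(sNC = 1, pNC = 1, `non-rMCI` = 0.2, rMCI = 1),
    covariate_effects = list(age_slope = 0, tiv_slope = 0),
    rng_seed = rng_seed + 3)
  ana <- generate_cohort(acfg)
  lab <- transition_labels(ana$cohort, c("non-rMCI", "rMCI"))

  scored <- score_cohort(ana$maps, model)
  ft_s <- build_features_from_scores(scored, model, labels = lab)
  rep_s <- cross_validated_rf(ft_s, n_folds = 5, n_trees = 500,
                              rng_seed = rng_seed + 4)

  atlas <- sim_atlas(acfg)
  ft_r <- build_features_from_regions(ana$maps, atlas, region_ids = 1L,
                                      labels = lab)
  rep_r <- cross_validated_rf(ft_r, n_folds = 5, n_trees = 500,
                              rng_seed = rng_seed + 4)
  list(auc_scores = rep_s$auc_mean, auc_region = rep_r$auc_mean,
       auc_gap = rep_s$auc_mean - rep_r$auc_mean,
       report_scores = rep_s, report_region = rep_r)
}
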