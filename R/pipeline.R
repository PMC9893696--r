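#' End-to-end pipeline configuration
#'
#' One object drives simulate -> build network -> score -> compare ->
#' predict -> report. Either supply a \code{sim_config} pair (template +
#' analysis cohorts are generated with disjoint ids) or file paths to
#' pre-existing images and phenotypes.
#'
#' @param simulation a \code{sim_config} for the analysis cohort, or NULL
#'   when \code{template_paths}/\code{analysis_paths} are given.
#' @param template_n_snc template cohort size (stable-normal participants
#'   used only to establish the network; default 65).
#' @param template_paths,analysis_paths optional lists with elements
#'   \code{images} (NIfTI paths) and \code{phenotypes} (CSV path).
#' @param seed_specs list of \code{seed_spec}; defaults to the simulation's
#'   planted seeds.
#' @param mask_threshold mean-density mask cutoff (0.2).
#' @param n_permutations,n_bootstraps resampling sizes (1000 each).
#' @param threshold_fraction retained top fraction (0.03).
#' @param contrasts list of group pairs to compare and predict.
#' @param rf list of random-forest settings: n_folds, n_trees, importance.
#' @param rng_seed master integer seed, recorded in every output.
#' @param output_dir where artifacts are written.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            template_n_snc = 65L,
                            template_paths = NULL,
                            analysis_paths = NULL,
                            seed_specs = NULL,
                            mask_threshold = 0.2,
                            n_permutations = 1000,
                            n_bootstraps = 1000,
                            threshold_fraction = 0.03,
                            contrasts = list(c("sNC", "pNC"),
                                             c("non-rMCI", "rMCI")),
                            rf = list(n_folds = 5, n_trees = 500,
                                      importance = "impurity"),
                            rng_seed = 0L,
                            output_dir = "scn_out") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full covariance-network pipeline
#'
#' Stages: (1) obtain template and analysis cohorts (simulated or loaded),
#' enforcing that the template is disjoint from the analysis cohort; (2)
#' build one covariance network model per seed spec on the template; (3)
#' score the analysis cohort; (4) covariate-adjusted group comparisons; (5)
#' random-forest prediction per contrast from score-map features; (6) write
#' artifacts under \code{output_dir} plus a manifest with per-file
#' checksums. All stages derive their randomness from \code{rng_seed}, so a
#' repeated run reproduces identical artifacts.
#'
#' @param config a \code{pipeline_config}.
#' @return the manifest, invisibly (list; also written as manifest.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  for (d in c("models", "scores", "comparisons", "predictions")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }

  if (!is.null(config$analysis_paths)) {
    tmpl <- load_cohort(config$template_paths$images,
                        config$template_paths$phenotypes)
    ana <- load_cohort(config$analysis_paths$images,
                       config$analysis_paths$phenotypes)
  } else {
    scfg <- config$simulation
    tcfg <- scfg
    tcfg$n_per_group <- c(sNC = as.integer(config$template_n_snc))
    tcfg$rng_seed <- scfg$rng_seed + 1L
    tmpl <- generate_cohort(tcfg)
    tmpl$cohort$participant_id <-
      paste0("tmpl-", tmpl$cohort$participant_id)
    for (i in seq_along(tmpl$maps)) {
      tmpl$maps[[i]]$participant_id <- tmpl$cohort$participant_id[i]
    }
    ana <- generate_cohort(scfg)
  }
  overlap <- intersect(tmpl$cohort$participant_id, ana$cohort$participant_id)
  if (length(overlap)) {
    stop("template and analysis cohorts overlap: ",
         paste(overlap, collapse = ", "))
  }

  specs <- config$seed_specs
  if (is.null(specs)) specs <- list(sim_seed_spec(config$simulation))
  mask <- make_mask(tmpl$maps, config$mask_threshold)

  models <- list(); all_scores <- list(); comparisons <- list()
  predictions <- list()
  for (spec in specs) {
    nm <- spec$network_name
    model <- build_network(tmpl$maps, spec, mask,
                           n_permutations = config$n_permutations,
                           n_bootstraps = config$n_bootstraps,
                           threshold_fraction = config$threshold_fraction,
                           rng_seed = config$rng_seed)
    write_network_model(model, file.path(out, "models", nm))
    models[[nm]] <- model

    scored <- score_cohort(ana$maps, model)
    utils::write.csv(cbind(scored$scores, rng_seed = config$rng_seed),
                     file.path(out, "scores", paste0(nm, "_scores.csv")),
                     row.names = FALSE)
    all_scores[[nm]] <- scored

    for (ct in config$contrasts) {
      key <- paste(nm, ct[1], "vs", ct[2], sep = "_")
      cmp <- ancova_compare(scored$scores$composite_score, ana$cohort,
                            contrast = ct)
      comparisons[[key]] <- cmp
      lab <- transition_labels(ana$cohort, ct)
      rows <- attr(lab, "rows")
      ft <- build_features_from_scores(
        list(scores = scored$scores[rows, ],
             score_matrix = scored$score_matrix[rows, , drop = FALSE]),
        model, labels = lab)
      rep_ <- cross_validated_rf(ft, n_folds = config$rf$n_folds,
                                 n_trees = config$rf$n_trees,
                                 rng_seed = config$rng_seed,
                                 importance = config$rf$importance)
      predictions[[key]] <- rep_
      jsonlite::write_json(
        list(contrast = ct, network = nm,
             auc_mean = rep_$auc_mean, auc_sd = rep_$auc_sd,
             fold_auc = rep_$fold_auc, pooled_auc = rep_$pooled_auc,
             sensitivity = rep_$sensitivity, specificity = rep_$specificity,
             roc_points = rep_$roc_points,
             n_folds = rep_$n_folds, n_trees = rep_$n_trees,
             rng_seed = config$rng_seed),
        file.path(out, "predictions", paste0(key, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  cmp_tab <- do.call(rbind, lapply(names(comparisons), function(k) {
    cmp <- comparisons[[k]]
    data.frame(comparison = k,
               F_statistic = cmp$F_statistic, p_value = cmp$p_value,
               mean_A = cmp$group_means$mean[1], sd_A = cmp$group_means$sd[1],
               mean_B = cmp$group_means$mean[2], sd_B = cmp$group_means$sd[2],
               adj_mean_A = cmp$adjusted_means[1],
               adj_mean_B = cmp$adjusted_means[2],
               rng_seed = config$rng_seed)
  }))
  utils::write.csv(cmp_tab, file.path(out, "comparisons", "ancova.csv"),
                   row.names = FALSE)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("scnet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    rng_seed = config$rng_seed,
    n_permutations = config$n_permutations,
    n_bootstraps = config$n_bootstraps,
    threshold_fraction = config$threshold_fraction,
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, models = models,
                 scores = all_scores, comparisons = comparisons,
                 predictions = predictions,
                 template = tmpl, analysis = ana))
}
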