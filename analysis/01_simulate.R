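#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohorts.
#
# Generates (a) a template cohort of 65 stable-normal participants used only
# to establish the covariance networks, and (b) an analysis cohort of
# 28 sNC / 18 pNC / 20 non-rMCI / 24 rMCI with group-dependent atrophy and
# covariance structure plus age/TIV covariate effects. Maps are written as
# NIfTI, phenotypes as CSV, planted ground truth as JSON.

suppressMessages(library(scnet))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tmpl_cfg <- sim_config(n_per_group = c(sNC = 65L), rng_seed = 101L)
ana_cfg <- sim_config(rng_seed = 102L)

write_cohort <- function(coh, prefix) {
  coh$cohort$participant_id <- paste0(prefix, coh$cohort$participant_id)
  for (i in seq_along(coh$maps)) {
    coh$maps[[i]]$participant_id <- coh$cohort$participant_id[i]
    write_gm_map(coh$maps[[i]],
                 file.path(out, paste0(coh$maps[[i]]$participant_id, ".nii.gz")))
  }
  utils::write.csv(coh$cohort, file.path(out, paste0(prefix, "phenotypes.csv")),
                   row.names = FALSE, quote = FALSE)
  coh
}

tmpl <- write_cohort(generate_cohort(tmpl_cfg), "tmpl-")
ana <- write_cohort(generate_cohort(ana_cfg), "ana-")

jsonlite::write_json(
  list(network_voxel_indices = ana$truth$network_voxel_indices,
       seed_voxel_indices = ana$truth$seed_voxel_indices,
       rng_seed_template = tmpl_cfg$rng_seed,
       rng_seed_analysis = ana_cfg$rng_seed),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
write_atlas(sim_atlas(ana_cfg), file.path(out, "atlas.nii.gz"),
            file.path(out, "atlas_labels.tsv"))

cat(sprintf("template: %d maps | analysis: %d maps (%s)\n",
            length(tmpl$maps), length(ana$maps),
            paste(sprintf("%s=%d", names(table(ana$cohort$group)),
                          table(ana$cohort$group)), collapse = ", ")))
cat(sprintf("grid %s at %g mm, %d planted network voxels\n",
            paste(ana_cfg$grid_shape, collapse = "x"), ana_cfg$voxel_size_mm,
            length(ana$truth$network_voxel_indices)))
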