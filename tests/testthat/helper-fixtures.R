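# Small in-code fixtures shared across test files.

# n random density maps on a tiny grid with a given affine
tiny_maps <- function(n = 3, dims = c(6, 6, 6), affine = NULL, seed = 1,
                      base = 0.5, sd = 0.05) {
  if (is.null(affine)) affine <- diag(4)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    gm_map(array(pmin(pmax(rnorm(prod(dims), base, sd), 0), 1), dims),
           affine, sprintf("sub-%03d", i))
  })
}

# phenotype table matching a list of maps
tiny_phenotypes <- function(maps, groups = NULL, seed = 1) {
  set.seed(seed)
  n <- length(maps)
  if (is.null(groups)) groups <- rep("sNC", n)
  data.frame(
    participant_id = vapply(maps, `[[`, "", "participant_id"),
    group = groups,
    age = round(rnorm(n, 70, 5), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education = round(rnorm(n, 12, 3)),
    tiv = round(rnorm(n, 1450, 100), 1),
    apoe4 = "unknown",
    stringsAsFactors = FALSE
  )
}

# write maps + phenotypes to a temp dir; returns list(images, phenotypes)
write_tiny_cohort <- function(maps, pheno, dir = tempfile("cohort")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(maps, function(m) {
    p <- file.path(dir, paste0(m$participant_id, ".nii.gz"))
    write_gm_map(m, p)
    p
  }, "")
  pp <- file.path(dir, "phenotypes.csv")
  utils::write.csv(pheno, pp, row.names = FALSE, quote = FALSE)
  list(images = paths, phenotypes = pp, dir = dir)
}

# minimal hand-made network model over an arbitrary grid
toy_model <- function(voxel_index, weight, grid = c(6, 6, 6),
                      affine = diag(4)) {
  structure(list(
    seed_spec = seed_spec("custom",
                          data.frame(name = "s1", x = 0, y = 0, z = 0), 6),
    grid_shape = as.integer(grid),
    affine = affine,
    mask_index = seq_len(prod(grid)),
    lv = list(index = 1L, singular_value = 1, perm_p = 0.001,
              bsr = rep(1, prod(grid))),
    perm_p = 0.001,
    weight_map = list(voxel_index = as.integer(voxel_index),
                      weight = weight,
                      n_retained = length(voxel_index)),
    threshold_fraction = 0.03, weight_source = "salience",
    signed_threshold = FALSE,
    n_permutations = 100, n_bootstraps = 100,
    template_ids = character(), rng_seed = 0
  ), class = "scn_model")
}
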