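test_that("seed extraction averages exactly the in-sphere voxels", {
  g <- c(12, 12, 12)
  aff <- diag(c(4, 4, 4, 1)); aff[1:3, 4] <- c(-40, -36, -26)
  set.seed(3)
  maps <- lapply(1:4, function(i)
    gm_map(array(runif(prod(g)), g), aff, paste0("p", i)))
  # left hippocampal seed coordinate, radius 6 mm
  spec <- seed_spec("HN", data.frame(name = "HIP_L",
                                     x = -25, y = -21, z = -10), 6)
  S <- extract_seed_matrix(maps, spec)
  # brute-force oracle: distance of every voxel centre to the coordinate
  idx <- as.matrix(expand.grid(i = 0:11, j = 0:11, k = 0:11))
  mm <- sweep(idx %*% t(aff[1:3, 1:3]), 2, aff[1:3, 4], `+`)
  sel <- which(colSums((t(mm) - c(-25, -21, -10))^2) <= 36)
  expect_gt(length(sel), 1)
  for (i in 1:4) expect_equal(S[i, 1], mean(maps[[i]]$data[sel]))

  uni <- lapply(1:3, function(i) gm_map(array(0.5, g), aff, paste0("u", i)))
  expect_error(extract_seed_matrix(uni, spec), "zero variance")

  # radius below half the voxel size isolates a single voxel
  tiny <- seed_spec("custom", data.frame(name = "pt", x = 0, y = 0, z = 2), 1.5)
  S1 <- extract_seed_matrix(maps, tiny)
  vox <- mni_to_voxel(c(0, 0, 2), aff)
  for (i in 1:4) expect_equal(S1[i, 1], maps[[i]]$data[vox[1]+1, vox[2]+1, vox[3]+1])

  far <- seed_spec("custom", data.frame(name = "out", x = 500, y = 0, z = 0), 3)
  expect_error(extract_seed_matrix(maps, far), "out")
})

test_that("seed-voxel correlation matches the Pearson formula and its bounds", {
  g <- c(3, 3, 1)
  set.seed(7)
  vals <- matrix(runif(5 * 9), 5, 9)
  seedcol <- vals[, 5]
  vals[, 1] <- seedcol                 # identical voxel
  vals[, 2] <- 1 - seedcol             # negated, mean-shifted
  maps <- lapply(1:5, function(i) gm_map(array(vals[i, ], g), diag(4), paste0("p", i)))
  mask <- make_mask(maps, 0)
  S <- matrix(seedcol, ncol = 1, dimnames = list(NULL, "s"))
  R <- seed_voxel_correlation(S, maps, mask)
  expect_equal(unname(R[1, 1]), 1)
  expect_equal(unname(R[1, 2]), -1)
  # textbook formula oracle at one arbitrary voxel
  x <- seedcol; y <- vals[, 7]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(R[1, 7]), r_hand, tolerance = 1e-12)
  expect_true(all(R >= -1 & R <= 1))
  expect_error(seed_voxel_correlation(S[1:2, , drop = FALSE], maps[1:2], mask),
               "3 participants")
})

test_that("decomposition obeys the rank-1 closed form and reconstructs exactly", {
  set.seed(9)
  row <- rnorm(8)
  lv <- decompose(matrix(row, 1))[[1]]
  expect_equal(lv$singular_value, sqrt(sum(row^2)))
  sgn <- if (sum(row) < 0) -1 else 1
  expect_equal(lv$voxel_salience, sgn * row / sqrt(sum(row^2)), tolerance = 1e-12)
  expect_gte(sum(lv$voxel_salience), 0)

  R <- matrix(rnorm(12), 2, 6)
  lvs <- decompose(R)
  rec <- Reduce(`+`, lapply(lvs, function(l)
    l$singular_value * outer(l$seed_salience, l$voxel_salience)))
  expect_lt(max(abs(rec - R)), 1e-10)
  expect_true(lvs[[1]]$singular_value >= lvs[[2]]$singular_value)
  for (l in lvs) {
    expect_equal(sum(l$voxel_salience^2), 1, tolerance = 1e-10)
    expect_equal(sum(l$seed_salience^2), 1, tolerance = 1e-10)
  }

  r1 <- outer(c(1, 2), rnorm(6))        # rank one
  expect_lt(decompose(r1)[[2]]$singular_value, 1e-10)
})

test_that("single-seed LV1 salience is the normalised correlation vector", {
  cfg <- planted_config(n = 30, rng_seed = 13)
  coh <- generate_cohort(cfg)
  mask <- make_mask(coh$maps)
  ctr <- cfg$seed_centers[1, , drop = FALSE]
  spec <- seed_spec("custom",
                    data.frame(name = "s1", x = ctr[1], y = ctr[2], z = ctr[3]),
                    cfg$seed_radius_mm)
  S <- extract_seed_matrix(coh$maps, spec)
  R <- seed_voxel_correlation(S, coh$maps, mask)
  lv <- decompose(R)[[1]]
  cossim <- sum(lv$voxel_salience * R[1, ]) /
    sqrt(sum(R[1, ]^2))
  expect_gt(abs(cossim), 1 - 1e-10)
})

test_that("permutation p-values hit the (k+1)/(N+1) floor for strong signal", {
  cfg <- planted_config(n = 40, rng_seed = 19)
  coh <- generate_cohort(cfg)
  mask <- make_mask(coh$maps)
  pt <- permutation_test(coh$maps, sim_seed_spec(cfg), mask,
                         n_permutations = 100, rng_seed = 5)
  expect_equal(pt$perm_p[1], 1 / 101)
  pt2 <- permutation_test(coh$maps, sim_seed_spec(cfg), mask,
                          n_permutations = 100, rng_seed = 5)
  expect_identical(pt, pt2)
  expect_error(permutation_test(coh$maps, sim_seed_spec(cfg), mask,
                                n_permutations = 50), "n_permutations")
})

test_that("bootstrap ratios separate planted voxels from pure noise", {
  cfg <- planted_config(n = 40, rng_seed = 23)
  coh <- generate_cohort(cfg)
  mask <- make_mask(coh$maps)
  spec <- sim_seed_spec(cfg)
  b <- bootstrap_bsr(coh$maps, spec, mask, n_bootstraps = 150, rng_seed = 2)
  excl <- scnet:::.seed_excluded_index(mask, spec, coh$maps[[1]]$affine)
  net <- excl$index %in% coh$truth$network_voxel_indices
  noise <- excl$index %in% coh$truth$noise_voxel_indices
  expect_gt(median(abs(b$bsr[net])),
            quantile(abs(b$bsr[noise]), 0.97))
  expect_false(any(b$degenerate[net]))
  # degenerate voxels (zero bootstrap se) get bsr 0 by convention
  expect_true(all(b$bsr[b$degenerate] == 0))
})

test_that("thresholding keeps the exact count with nested, deterministic support", {
  set.seed(31)
  lv <- list(voxel_salience = rnorm(100), bsr = rnorm(100))
  idx <- 101:200
  wm <- threshold_network(lv, 0.03, idx)
  expect_equal(wm$n_retained, 3)
  expect_length(wm$voxel_index, 3)
  expect_true(all(wm$voxel_index %in% idx))
  # weights are the salience values of the retained voxels
  expect_equal(wm$weight, lv$voxel_salience[wm$voxel_index - 100])
  w1 <- threshold_network(lv, 0.01, idx)
  w3 <- threshold_network(lv, 0.03, idx)
  w5 <- threshold_network(lv, 0.05, idx)
  expect_true(all(w1$voxel_index %in% w3$voxel_index))
  expect_true(all(w3$voxel_index %in% w5$voxel_index))
  # signed thresholding keeps only positive-BSR voxels at the top
  ws <- threshold_network(lv, 0.05, idx, signed = TRUE)
  expect_true(all(lv$bsr[ws$voxel_index - 100] >=
                    sort(lv$bsr, decreasing = TRUE)[5] - 1e-12))
})

test_that("correlations, saliences and BSR are invariant to density rescaling", {
  cfg <- planted_config(n = 25, rng_seed = 37)
  coh <- generate_cohort(cfg)
  mask <- make_mask(coh$maps)
  spec <- sim_seed_spec(cfg)
  scaled <- lapply(coh$maps, function(m) {
    m$data <- m$data * 0.5   # positive rescaling
    m
  })
  S1 <- extract_seed_matrix(coh$maps, spec)
  S2 <- extract_seed_matrix(scaled, spec)
  R1 <- seed_voxel_correlation(S1, coh$maps, mask)
  R2 <- seed_voxel_correlation(S2, scaled, mask)
  expect_equal(R1, R2, tolerance = 1e-10)
  b1 <- bootstrap_bsr(coh$maps, spec, mask, n_bootstraps = 100, rng_seed = 4)
  b2 <- bootstrap_bsr(scaled, spec, mask, n_bootstraps = 100, rng_seed = 4)
  expect_equal(b1$bsr, b2$bsr, tolerance = 1e-8)
  expect_equal(b1$voxel_salience, b2$voxel_salience, tolerance = 1e-10)
})

test_that("build_network is deterministic and refuses a non-significant LV1", {
  cfg <- planted_config(n = 30, rng_seed = 41)
  coh <- generate_cohort(cfg)
  mask <- make_mask(coh$maps)
  m1 <- build_network(coh$maps, sim_seed_spec(cfg), mask,
                      n_permutations = 100, n_bootstraps = 100, rng_seed = 6)
  m2 <- build_network(coh$maps, sim_seed_spec(cfg), mask,
                      n_permutations = 100, n_bootstraps = 100, rng_seed = 6)
  expect_identical(m1$weight_map, m2$weight_map)
  expect_identical(m1$lv$bsr, m2$lv$bsr)
  expect_identical(m1$perm_p, m2$perm_p)

  nullcoh <- generate_null_cohort(planted_config(n = 30, rng_seed = 43))
  nmask <- make_mask(nullcoh$maps)
  expect_error(
    build_network(nullcoh$maps, sim_seed_spec(cfg), nmask,
                  n_permutations = 100, n_bootstraps = 100, rng_seed = 7),
    "not significant")
  expect_warning(
    build_network(nullcoh$maps, sim_seed_spec(cfg), nmask,
                  n_permutations = 100, n_bootstraps = 100, rng_seed = 7,
                  allow_nonsignificant = TRUE),
    "not significant")
})

test_that("network models survive a write/read round trip", {
  cfg <- planted_config(n = 25, rng_seed = 47)
  coh <- generate_cohort(cfg)
  m <- build_network(coh$maps, sim_seed_spec(cfg), make_mask(coh$maps),
                     n_permutations = 100, n_bootstraps = 100, rng_seed = 8)
  d <- withr::local_tempdir()
  write_network_model(m, d)
  back <- read_network_model(d)
  expect_equal(back$weight_map$voxel_index, m$weight_map$voxel_index)
  expect_equal(back$weight_map$weight, m$weight_map$weight, tolerance = 1e-12)
  expect_equal(back$lv$bsr, unname(m$lv$bsr), tolerance = 1e-6)
  expect_equal(back$perm_p, m$perm_p)
  expect_equal(back$affine, m$affine)
  # a scored participant gives the same composite under the reloaded model
  s1 <- score_map(coh$maps[[1]], m)
  s2 <- score_map(coh$maps[[1]], back)
  expect_equal(s1$composite_score, s2$composite_score, tolerance = 1e-10)
})
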