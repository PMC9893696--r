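test_that("AUC equals brute-force Mann-Whitney pair counting", {
  lab <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  sc <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.2)
  out <- compute_roc(lab, sc)
  # brute force over all (negative, positive) pairs, ties count one half
  tot <- 0; npairs <- 0
  for (i in which(!lab)) for (j in which(lab)) {
    npairs <- npairs + 1
    tot <- tot + (sc[j] > sc[i]) + 0.5 * (sc[j] == sc[i])
  }
  expect_equal(out$auc, tot / npairs)
  expect_equal(compute_roc(lab, as.numeric(lab))$auc, 1)
  expect_equal(compute_roc(lab, rep(0.7, 6))$auc, 0.5)
  expect_error(compute_roc(rep(TRUE, 4), rnorm(4)), "classes")
  # curve is monotone and spans (0,0) to (1,1)
  expect_true(all(diff(out$roc_points$fpr) >= 0))
  expect_true(all(diff(out$roc_points$tpr) >= 0))
  expect_equal(out$roc_points$fpr[1], 0)
  expect_equal(utils::tail(out$roc_points$tpr, 1), 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(17)
  for (i in 1:5) {
    lab <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(40, mean = lab), 1)   # induces ties
    ours <- compute_roc(lab, sc)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("feature tables index voxels and regions faithfully", {
  g <- c(6, 6, 6)
  model <- toy_model(voxel_index = c(5L, 60L, 200L), weight = c(1, 2, 3),
                     grid = g)
  set.seed(21)
  maps <- tiny_maps(10, dims = g, seed = 21)
  scored <- score_cohort(maps, model)
  ft <- build_features_from_scores(scored, model)
  expect_equal(dim(ft$x), c(10L, 3L))
  expect_equal(ft$feature_ids, c(5L, 60L, 200L))
  for (i in c(1, 4, 10)) {
    expect_equal(unname(ft$x[i, ]),
                 unname(score_map(maps[[i]], model)$score))
  }
  # permuting participants permutes rows only
  perm <- c(3, 1, 2, 5, 4, 7, 6, 10, 9, 8)
  scored_p <- score_cohort(maps[perm], model)
  ft_p <- build_features_from_scores(scored_p, model)
  expect_equal(unname(ft_p$x), unname(ft$x[perm, ]))

  lab <- array(0L, g); lab[1:3, , ] <- 1L; lab[4:6, 1:2, ] <- 2L
  atlas <- atlas_volume(lab, c(`1` = "hippocampus", `2` = "pcc"), diag(4))
  fr <- build_features_from_regions(maps, atlas, c(1L, 2L))
  expect_equal(ncol(fr$x), 2L)
  loop <- t(vapply(maps, function(m)
    c(mean(m$data[lab == 1L]), mean(m$data[lab == 2L])), numeric(2)))
  expect_equal(unname(fr$x), unname(loop), tolerance = 1e-12)
  fr1 <- build_features_from_regions(maps, atlas, 1L)
  expect_equal(ncol(fr1$x), 1L)
  const <- lapply(1:4, function(i) gm_map(array(0.5, g), diag(4), paste0("c", i)))
  expect_message(build_features_from_regions(const, atlas, 1L),
                 "zero-variance")
})

test_that("cross-validated forest is calibrated, powerful, and deterministic", {
  set.seed(25)
  n <- 100
  noise <- matrix(rnorm(n * 8), n)
  lab <- factor(rep(c("a", "b"), each = n / 2))
  ftab <- scnet:::.feature_table(noise, seq_len(8), lab, "voxel")
  rep0 <- cross_validated_rf(ftab, n_folds = 5, n_trees = 300, rng_seed = 1)
  expect_gte(rep0$auc_mean, 0.35)
  expect_lte(rep0$auc_mean, 0.65)
  expect_equal(rep0$n_folds, 5)

  sep <- cbind(c(rnorm(n / 2, -3), rnorm(n / 2, 3)), noise[, 1:3])
  ftab2 <- scnet:::.feature_table(sep, 1:4, lab, "voxel")
  rep1 <- cross_validated_rf(ftab2, n_folds = 5, n_trees = 300, rng_seed = 1)
  expect_gte(rep1$auc_mean, 0.99)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)

  rep2 <- cross_validated_rf(ftab, n_folds = 5, n_trees = 300, rng_seed = 1)
  expect_identical(rep0, rep2)

  tiny <- scnet:::.feature_table(noise[1:6, ], 1:8,
                                 factor(c("a", "a", "a", "a", "b", "b")),
                                 "voxel")
  expect_error(cross_validated_rf(tiny, n_folds = 5), "fewer")
})

test_that("importance is normalised, symmetric under pure noise, and finds signal", {
  set.seed(29)
  n <- 200
  lab <- factor(rep(c("a", "b"), each = n / 2))
  noise <- matrix(rnorm(n * 10), n)
  ftab <- scnet:::.feature_table(noise, 1:10, lab, "voxel")
  rep0 <- cross_validated_rf(ftab, n_folds = 5, n_trees = 500, rng_seed = 3)
  imp <- importance_map(rep0)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_lt(max(imp) / min(imp), 3)

  signal <- c(rnorm(n / 2, 0), rnorm(n / 2, 1.5))
  x <- cbind(signal, matrix(rnorm(n * 20), n))
  ftab2 <- scnet:::.feature_table(x, 1:21, lab, "voxel")
  rep1 <- cross_validated_rf(ftab2, n_folds = 5, n_trees = 500, rng_seed = 3)
  imp1 <- importance_map(rep1)
  expect_equal(names(which.max(imp1)), "1")

  # volume rendering and atlas aggregation put mass where the voxels are
  g <- c(6, 6, 6)
  model <- toy_model(voxel_index = c(2L, 8L, 30L), weight = c(1, 1, 1), grid = g)
  imp_v <- stats::setNames(c(0.5, 0.3, 0.2), c("2", "8", "30"))
  vol <- importance_volume(imp_v, model)
  expect_equal(vol[2], 0.5); expect_equal(sum(vol), 1)
  lab3 <- array(0L, g); lab3[1:10] <- 1L; lab3[25:36] <- 2L
  atl <- atlas_volume(lab3, c(`1` = "hippocampus", `2` = "precuneus"), diag(4))
  agg <- aggregate_importance(imp_v, atl, top_n = 10)
  expect_equal(agg$importance[agg$region_name == "hippocampus"], 0.8)
  expect_equal(agg$region_name[1], "hippocampus")
})

test_that("transition labels select the contrast rows with the positive class second", {
  cohort <- data.frame(group = c("sNC", "pNC", "rMCI", "sNC", "pNC"))
  lab <- transition_labels(cohort, c("sNC", "pNC"))
  expect_equal(attr(lab, "rows"), c(1L, 2L, 4L, 5L))
  expect_equal(levels(lab), c("sNC", "pNC"))
  expect_error(transition_labels(data.frame(group = c("sNC", "sNC")),
                                 c("sNC", "pNC")), "both")
})
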