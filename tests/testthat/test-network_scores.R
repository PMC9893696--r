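test_that("score maps are the density-weight products on the support", {
  g <- c(6, 6, 6)
  model <- toy_model(voxel_index = c(10L, 50L, 120L), weight = c(2, -1, 0.5),
                     grid = g)
  zero <- gm_map(array(0, g), diag(4), "z")
  expect_equal(score_map(zero, model)$composite_score, 0)

  one <- toy_model(voxel_index = 10L, weight = 2, grid = g)
  half <- gm_map(array(0, g), diag(4), "h")
  half$data[10] <- 0.5
  expect_equal(score_map(half, one)$composite_score, 1.0)

  set.seed(2)
  m <- gm_map(array(runif(prod(g)), g), diag(4), "r")
  sr <- score_map(m, model)
  expect_equal(sr$score, m$data[model$weight_map$voxel_index] *
                 model$weight_map$weight, tolerance = 1e-15)
  expect_equal(sr$composite_score, sum(sr$score), tolerance = 1e-10)

  wrong <- gm_map(array(0.2, c(5, 6, 6)), diag(4), "w")
  expect_error(score_map(wrong, model), "grid")
})

test_that("scoring is linear and blind to off-support voxels", {
  g <- c(6, 6, 6)
  model <- toy_model(voxel_index = c(3L, 77L, 140L), weight = c(1.5, 0.7, -0.2),
                     grid = g)
  set.seed(4)
  a <- gm_map(array(runif(prod(g), 0, 0.4), g), diag(4), "a")
  b <- gm_map(array(runif(prod(g), 0, 0.4), g), diag(4), "b")
  ab <- gm_map(array(a$data + b$data, g), diag(4), "ab")
  sa <- score_map(a, model); sb <- score_map(b, model); sab <- score_map(ab, model)
  expect_equal(sa$score + sb$score, sab$score, tolerance = 1e-12)
  expect_equal(sa$composite_score + sb$composite_score, sab$composite_score,
               tolerance = 1e-10)

  pert <- a
  off <- setdiff(seq_len(prod(g)), model$weight_map$voxel_index)
  pert$data[off] <- runif(length(off))
  expect_identical(score_map(pert, model)$composite_score, sa$composite_score)
})

test_that("ancova F matches an independent residualisation oracle", {
  # 8-row hand-made table
  d <- data.frame(
    participant_id = paste0("p", 1:8),
    group = rep(c("sNC", "pNC"), each = 4),
    age = c(66, 71, 68, 74, 70, 65, 72, 69),
    sex = c("M", "F", "M", "F", "F", "M", "F", "M"),
    education = c(12, 16, 10, 14, 12, 18, 9, 15),
    tiv = c(1400, 1520, 1380, 1450, 1490, 1410, 1550, 1430),
    apoe4 = "unknown", stringsAsFactors = FALSE
  )
  score <- c(10.2, 11.5, 9.8, 12.1, 9.1, 8.7, 10.0, 9.4)
  res <- ancova_compare(score, d, c("sNC", "pNC"), covariates = c("age", "tiv"))

  # oracle: residualise score and group indicator on covariates, then F of
  # the simple regression of residual on residual
  Z <- cbind(1, d$age, d$tiv)
  gi <- as.numeric(d$group == "pNC")
  ry <- score - Z %*% solve(crossprod(Z), crossprod(Z, score))
  rg <- gi - Z %*% solve(crossprod(Z), crossprod(Z, gi))
  bh <- sum(ry * rg) / sum(rg^2)
  rss1 <- sum((ry - bh * rg)^2)
  rss0 <- sum(ry^2)
  df2 <- 8 - ncol(Z) - 1
  F_oracle <- (rss0 - rss1) / (rss1 / df2)
  p_oracle <- pf(F_oracle, 1, df2, lower.tail = FALSE)
  expect_equal(res$F_statistic, F_oracle, tolerance = 1e-8)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-8)
  expect_equal(unname(res$df), c(1, df2))
})

test_that("without covariates the ancova F equals the pooled t squared", {
  set.seed(6)
  d <- data.frame(
    participant_id = paste0("p", 1:30),
    group = rep(c("non-rMCI", "rMCI"), c(14, 16)),
    age = rnorm(30, 70, 5), sex = sample(c("M", "F"), 30, TRUE),
    education = rnorm(30, 12, 2), tiv = rnorm(30, 1450, 100),
    apoe4 = "unknown", stringsAsFactors = FALSE
  )
  score <- rnorm(30, ifelse(d$group == "rMCI", 11, 10), 1.3)
  res <- ancova_compare(score, d, c("non-rMCI", "rMCI"), covariates = character())
  tt <- t.test(score ~ factor(d$group, c("non-rMCI", "rMCI")),
               var.equal = TRUE)
  expect_equal(res$F_statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-8)
  # raw group means are reported alongside the adjusted ones
  expect_equal(res$group_means$mean,
               c(mean(score[d$group == "non-rMCI"]),
                 mean(score[d$group == "rMCI"])))
  expect_equal(unname(res$adjusted_means), res$group_means$mean)
})

test_that("ancova rejects rank-deficient designs by name", {
  d <- data.frame(
    participant_id = paste0("p", 1:10),
    group = rep(c("sNC", "pNC"), 5),
    age = 1:10, sex = "M", education = 2 * (1:10),  # education = 2*age
    tiv = rnorm(10, 1450, 50), apoe4 = "unknown", stringsAsFactors = FALSE
  )
  expect_error(
    ancova_compare(rnorm(10), d, c("sNC", "pNC"),
                   covariates = c("age", "education")),
    "education")
})

test_that("score-density correlation matches the direct formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(score_density_correlation(x, x)$r, 1)
  y <- c(0.42, 0.38, 0.45, 0.40, 0.50)
  out <- score_density_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), 3), tolerance = 1e-10)
  expect_error(score_density_correlation(c(1, 1, 1), y[1:3]), "variance")
  expect_error(score_density_correlation(x[1:2], y[1:2]), "3 pairs")
})

test_that("composite scores track planted hippocampal density and group order", {
  cfg <- planted_config(n = 100, rng_seed = 55)
  coh <- generate_cohort(cfg)
  model <- build_network(coh$maps[1:50], sim_seed_spec(cfg),
                         make_mask(coh$maps[1:50]),
                         n_permutations = 100, n_bootstraps = 100,
                         rng_seed = 9)
  rest <- coh$maps[51:100]
  scored <- score_cohort(rest, model)
  atlas <- sim_atlas(cfg)
  hip <- vapply(rest, function(m)
    unname(region_mean_density(m, atlas, 1L)), 0)
  out <- score_density_correlation(scored$scores$composite_score, hip)
  expect_gt(out$r, 0.5)
})

test_that("planted group ordering is recovered by adjusted means", {
  correct <- vapply(1:5, function(i) {
    cfg <- sim_config(
      n_per_group = c(`non-rMCI` = 50, rMCI = 50),
      lambda = 0.25, noise_sd = 0.5,
      group_mean_shift = c(sNC = 0, pNC = 0, `non-rMCI` = -0.25, rMCI = 0),
      covariate_effects = list(age_slope = 0, tiv_slope = 0),
      rng_seed = 60 + i)
    coh <- generate_cohort(cfg)
    tmpl <- generate_cohort(planted_config(n = 30, rng_seed = 80 + i,
                                           lambda = 0.25))
    model <- build_network(tmpl$maps, sim_seed_spec(cfg), NULL,
                           n_permutations = 100, n_bootstraps = 100,
                           rng_seed = i)
    scored <- score_cohort(coh$maps, model)
    cmp <- ancova_compare(scored$scores$composite_score,
                          coh$cohort, c("non-rMCI", "rMCI"))
    cmp$adjusted_means["non-rMCI"] < cmp$adjusted_means["rMCI"]
  }, logical(1))
  expect_true(all(correct))
})
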