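#' Simulation configuration for synthetic grey-matter cohorts
#'
#' The generator emulates smoothed voxel-based-morphometry grey-matter density
#' maps in which a set of compact "network" blobs shares a latent anatomical
#' factor with seed blobs (structural covariance). Per participant i with
#' latent factor f_i ~ N(0,1), a signal voxel in blob b takes the value
#'
#'   base + signal_scale * ( loading(g) * lambda * g_ib + delta(g) + cov_i + e )
#'
#' with g_ib = sqrt(sync(g)) * f_i + sqrt(1 - sync(g)) * h_ib (h_ib a
#' blob-private factor, so \code{group_sync < 1} models loss of atrophy
#' synchrony at unchanged marginal variance), delta(g) a group mean shift
#' (atrophy), cov_i the age/TIV covariate term, and e ~ N(0, noise_sd) i.i.d.
#' voxel noise. Background voxels carry only base + covariates + noise. The
#' volume is then Gaussian-smoothed to \code{smoothing_fwhm_mm} and clamped
#' to [0,1]. \code{lambda}, \code{noise_sd} and the group shifts are
#' dimensionless signal units; \code{signal_scale} converts them to density
#' units small enough that clamping is negligible, which keeps the factor
#' model's closed-form covariance exact.
#'
#' Group defaults are calibrated so that composite-score group effect sizes
#' at the default sample sizes land in the range reported for real
#' progression/reversion cohorts of this scale (Cohen's d roughly 0.7 for
#' sNC vs pNC and 0.8 for non-rMCI vs rMCI).
#'
#' @param grid_shape length-3 integer, default 24x24x24 voxels.
#' @param voxel_size_mm isotropic voxel size, default 4.
#' @param n_per_group named counts over \code{sNC, pNC, non-rMCI, rMCI};
#'   defaults mirror a small ageing-cohort design (28/18/20/24).
#' @param seed_centers,network_centers matrices of MNI mm blob centres.
#' @param seed_radius_mm radius of seed blobs (default 6).
#' @param network_fraction fraction of grid voxels planted as network (0.03).
#' @param lambda shared-factor loading (signal units, default 1).
#' @param noise_sd voxelwise noise sd (signal units, default 0.5).
#' @param group_mean_shift named density offsets (signal units) on signal
#'   voxels.
#' @param group_loading_scale named multipliers on \code{lambda}.
#' @param group_sync named fraction in (0,1] of factor variance shared across
#'   blobs (1 = fully synchronous).
#' @param smoothing_fwhm_mm Gaussian smoothing FWHM, default 8.
#' @param covariate_effects list(age_slope, tiv_slope) on global density
#'   (signal units per year / per ml; the default age slope corresponds to
#'   roughly a quarter percent of grey matter per year).
#' @param base_density background density, default 0.5.
#' @param signal_scale density units per signal unit, default 0.12.
#' @param rng_seed integer seed; identical seeds give bit-identical cohorts.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(grid_shape = c(24L, 24L, 24L),
                       voxel_size_mm = 4,
                       n_per_group = c(sNC = 28L, pNC = 18L,
                                       `non-rMCI` = 20L, rMCI = 24L),
                       seed_centers = rbind(c(-20, -20, -8), c(20, -20, -8)),
                       network_centers = rbind(c(-28, 20, 12), c(28, 20, 12),
                                               c(-20, -36, 20), c(24, -32, 16)),
                       seed_radius_mm = 6,
                       network_fraction = 0.03,
                       lambda = 1,
                       noise_sd = 0.5,
                       group_mean_shift = c(sNC = 0, pNC = -0.7,
                                            `non-rMCI` = -1.0, rMCI = -0.2),
                       group_loading_scale = c(sNC = 1, pNC = 0.85,
                                               `non-rMCI` = 0.7, rMCI = 1),
                       group_sync = c(sNC = 1, pNC = 1,
                                      `non-rMCI` = 1, rMCI = 1),
                       smoothing_fwhm_mm = 8,
                       covariate_effects = list(age_slope = -0.02,
                                                tiv_slope = 0.0005),
                       base_density = 0.5,
                       signal_scale = 0.12,
                       rng_seed = 0L) {
  stopifnot(lambda >= 0, noise_sd > 0,
            network_fraction > 0, network_fraction < 1,
            seed_radius_mm > 0, all(n_per_group >= 0))
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              n_per_group = n_per_group,
              seed_centers = as.matrix(seed_centers),
              network_centers = as.matrix(network_centers),
              seed_radius_mm = seed_radius_mm,
              network_fraction = network_fraction,
              lambda = lambda, noise_sd = noise_sd,
              group_mean_shift = group_mean_shift,
              group_loading_scale = group_loading_scale,
              group_sync = group_sync,
              smoothing_fwhm_mm = smoothing_fwhm_mm,
              covariate_effects = covariate_effects,
              base_density = base_density,
              signal_scale = signal_scale,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Affine of the synthetic grid (origin at the central voxel)
#' @param config a \code{sim_config}.
#' @export
sim_affine <- function(config) {
  aff <- diag(c(rep(config$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -config$voxel_size_mm * (config$grid_shape %/% 2)
  aff
}

# mm coordinates of every voxel centre, V x 3 (column-major voxel order)
.voxel_mm_grid <- function(config) {
  aff <- sim_affine(config)
  g <- config$grid_shape
  idx <- as.matrix(expand.grid(i = 0:(g[1] - 1), j = 0:(g[2] - 1),
                               k = 0:(g[3] - 1)))
  sweep(idx %*% t(aff[1:3, 1:3]), 2, aff[1:3, 4], `+`)
}

# blob geometry: `blob` assigns every signal voxel to a spatial cluster
# (1..S seed-anchored clusters, S+1..S+K distal clusters; 0 background);
# `role` distinguishes seed voxels (1) from planted network voxels (2).
# Seed blobs are spheres of seed_radius_mm; the network_fraction*V network
# voxels are grown jointly as the voxels nearest to any centre (seed or
# distal), so each seed is surrounded by a network annulus — covariance
# networks include the seed's own surround — and the remainder forms compact
# distal blobs that smoothing cannot destroy.
.blob_geometry <- function(config) {
  mm <- .voxel_mm_grid(config)
  V <- nrow(mm)
  S <- nrow(config$seed_centers)
  K <- nrow(config$network_centers)
  centers <- rbind(config$seed_centers, config$network_centers)
  d2 <- matrix(0, V, S + K)
  for (k in seq_len(S + K)) {
    d2[, k] <- colSums((t(mm) - centers[k, ])^2)
  }
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_len(V), nearest)]
  blob <- integer(V)
  role <- integer(V)
  for (s in seq_len(S)) {
    in_seed <- d2[, s] <= config$seed_radius_mm^2
    blob[in_seed] <- s
    role[in_seed] <- 1L
  }
  n_net <- round(config$network_fraction * V)
  free <- which(role == 0L)
  ord <- free[order(dmin[free], free)]
  chosen <- ord[seq_len(min(n_net, length(ord)))]
  blob[chosen] <- nearest[chosen]
  role[chosen] <- 2L
  list(blob = blob, role = role, n_blobs = S + K)
}

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Truncated (3 sd) kernel, rows renormalised at the boundary so constant
#' fields are preserved exactly.
#'
#' @param arr 3-D numeric array.
#' @param fwhm_mm full-width-half-maximum in mm; 0 disables smoothing.
#' @param voxel_size_mm isotropic voxel size.
#' @export
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(arr)
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(arr)
  K <- lapply(d, .smooth_matrix, sd_vox = sd_vox)
  arr <- array(K[[1]] %*% matrix(arr, d[1], d[2] * d[3]), d)
  p <- aperm(arr, c(2, 1, 3))
  p <- array(K[[2]] %*% matrix(p, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
  arr <- aperm(p, c(2, 1, 3))
  p <- aperm(arr, c(3, 1, 2))
  p <- array(K[[3]] %*% matrix(p, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
  aperm(p, c(2, 3, 1))
}

.smooth_matrix <- function(n, sd_vox) {
  r <- max(1L, ceiling(3 * sd_vox))
  i <- matrix(seq_len(n), n, n)
  w <- exp(-((i - t(i))^2) / (2 * sd_vox^2))
  w[abs(i - t(i)) > r] <- 0
  w / rowSums(w)
}

#' Generate a synthetic cohort of grey-matter density maps
#'
#' @param config a \code{sim_config}.
#' @return list with \code{maps} (list of \code{gm_map}), \code{cohort}
#'   (phenotype data.frame), \code{truth} (planted ground truth:
#'   \code{network_voxel_indices}, \code{seed_voxel_indices} as 1-based linear
#'   voxel indices, \code{latent_factor}, \code{blob_labels}) and
#'   \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  if (n < 1) stop("empty cohort requested")
  g <- config$grid_shape
  V <- prod(g)
  geo <- .blob_geometry(config)
  lab <- geo$blob
  n_blobs <- geo$n_blobs
  signal <- geo$role > 0L

  cohort <- data.frame(
    participant_id = sprintf("sub-%03d", seq_len(n)),
    group = groups,
    age = round(stats::rnorm(n, 70, 5), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education = pmax(0, round(stats::rnorm(n, 12, 3))),
    tiv = round(stats::rnorm(n, 1450, 120), 1),
    apoe4 = sample(c("noncarrier", "heterozygote", "homozygote"), n,
                   replace = TRUE, prob = c(0.7, 0.25, 0.05)),
    stringsAsFactors = FALSE
  )

  f <- stats::rnorm(n)                      # shared latent factor
  h <- matrix(stats::rnorm(n * n_blobs), n, n_blobs)  # blob-private factors
  aff <- sim_affine(config)
  ce <- config$covariate_effects
  cov_term <- ce$age_slope * (cohort$age - 70) + ce$tiv_slope * (cohort$tiv - 1450)

  maps <- vector("list", n)
  for (i in seq_len(n)) {
    gi <- groups[i]
    a <- config$group_loading_scale[[gi]]
    d <- config$group_mean_shift[[gi]]
    s <- config$group_sync[[gi]]
    raw <- rep(config$base_density + config$signal_scale * cov_term[i], V)
    blob_factor <- sqrt(s) * f[i] + sqrt(1 - s) * h[i, ]
    raw[signal] <- raw[signal] + config$signal_scale *
      (a * config$lambda * blob_factor[lab[signal]] + d)
    raw <- raw + config$signal_scale * stats::rnorm(V, 0, config$noise_sd)
    vol <- gaussian_smooth_3d(array(raw, g), config$smoothing_fwhm_mm,
                              config$voxel_size_mm)
    maps[[i]] <- gm_map(vol, aff, cohort$participant_id[i])
  }

  smoothed_signal <- gaussian_smooth_3d(array(as.numeric(signal), g),
                                        config$smoothing_fwhm_mm,
                                        config$voxel_size_mm)
  truth <- list(
    network_voxel_indices = which(geo$role == 2L),
    seed_voxel_indices = which(geo$role == 1L),
    halo_voxel_indices = which(geo$role == 0L & smoothed_signal > 0.01),
    noise_voxel_indices = which(geo$role == 0L & smoothed_signal <= 0.01),
    latent_factor = f,
    blob_labels = lab
  )
  list(maps = maps, cohort = cohort, truth = truth, config = config)
}

#' Generate a structureless (null) cohort
#'
#' Identical to \code{generate_cohort} with every source of between-voxel
#' association removed: latent factor, group effects, the global age/TIV
#' covariate terms (a global gradient is itself a true seed-voxel
#' association) and spatial smoothing (smoothed noise correlates a seed's
#' neighbourhood with the seed mean — again a true association, which a
#' correct permutation test must reject). What remains is i.i.d. voxel
#' noise, under which seed-voxel exchangeability holds exactly; used to
#' calibrate permutation inference.
#' @param config a \code{sim_config}.
#' @export
generate_null_cohort <- function(config) {
  config$lambda <- 0
  config$group_mean_shift[] <- 0
  config$group_loading_scale[] <- 1
  config$group_sync[] <- 1
  config$covariate_effects <- list(age_slope = 0, tiv_slope = 0)
  config$smoothing_fwhm_mm <- 0
  generate_cohort(config)
}

#' Seed specification matching a simulation's planted seed blobs
#' @param config a \code{sim_config}.
#' @export
sim_seed_spec <- function(config) {
  s <- config$seed_centers
  seed_spec("custom",
            data.frame(name = sprintf("seed_%d", seq_len(nrow(s))),
                       x = s[, 1], y = s[, 2], z = s[, 3]),
            radius_mm = config$seed_radius_mm)
}

#' Atlas labelling each planted blob as one region
#'
#' Seed-anchored clusters (seed sphere plus its network annulus) become
#' regions named \code{seed_*}; distal clusters \code{network_*};
#' background is 0.
#' @param config a \code{sim_config}.
#' @export
sim_atlas <- function(config) {
  geo <- .blob_geometry(config)
  S <- nrow(config$seed_centers)
  K <- nrow(config$network_centers)
  nm <- c(sprintf("seed_%d", seq_len(S)), sprintf("network_%d", seq_len(K)))
  atlas_volume(array(geo$blob, config$grid_shape),
               stats::setNames(nm, seq_len(S + K)),
               sim_affine(config))
}
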