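#' Seed specification for a covariance network
#'
#' @param network_name one of \code{"DMN"}, \code{"FPN"}, \code{"HN"},
#'   \code{"custom"}.
#' @param seeds data.frame with columns \code{name, x, y, z} (MNI mm).
#' @param radius_mm radius of the spherical seed region (default 6 mm; the
#'   seed extent is not standardised, so it is configurable).
#' @export
seed_spec <- function(network_name, seeds, radius_mm = 6) {
  stopifnot(network_name %in% c("DMN", "FPN", "HN", "custom"),
            nrow(seeds) >= 1, radius_mm > 0,
            all(c("name", "x", "y", "z") %in% names(seeds)))
  structure(list(network_name = network_name, seeds = seeds,
                 radius_mm = radius_mm),
            class = "seed_spec")
}

#' Canonical seeds of the default, frontoparietal and hippocampal networks
#'
#' Bilateral/paired MNI seed coordinates anchoring each network: DMN —
#' posterior inferior parietal lobule (-41, -60, 29) and posterior cingulate
#' cortex (-7, -52, 26); FPN — left (-36, 57, 9) and right (34, 52, 10)
#' anterior prefrontal cortex; HN — left (-25, -21, -10) and right
#' (29, -20, -10) hippocampus.
#'
#' @param network_name "DMN", "FPN" or "HN".
#' @param radius_mm seed sphere radius, default 6.
#' @return a \code{seed_spec}.
#' @export
network_seeds <- function(network_name, radius_mm = 6) {
  tab <- switch(network_name,
    DMN = data.frame(name = c("pIPL", "PCC"),
                     x = c(-41, -7), y = c(-60, -52), z = c(29, 26)),
    FPN = data.frame(name = c("aPFC_L", "aPFC_R"),
                     x = c(-36, 34), y = c(57, 52), z = c(9, 10)),
    HN  = data.frame(name = c("HIP_L", "HIP_R"),
                     x = c(-25, 29), y = c(-21, -20), z = c(-10, -10)),
    stop("unknown network '", network_name, "'"))
  seed_spec(network_name, tab, radius_mm)
}

#' Extract the participants-by-seeds matrix of mean seed densities
#'
#' Entry (i, s) is the mean density of map i over voxels whose centre lies
#' within \code{radius_mm} of seed s's MNI coordinate.
#'
#' @param maps list of \code{gm_map} on one grid.
#' @param spec a \code{seed_spec}.
#' @return numeric matrix (participants x seeds).
#' @export
extract_seed_matrix <- function(maps, spec) {
  aff <- maps[[1]]$affine
  g <- dim(maps[[1]]$data)
  mm <- .grid_mm(g, aff)
  S <- matrix(NA_real_, length(maps), nrow(spec$seeds))
  colnames(S) <- spec$seeds$name
  rownames(S) <- vapply(maps, `[[`, "", "participant_id")
  for (s in seq_len(nrow(spec$seeds))) {
    ctr <- as.numeric(spec$seeds[s, c("x", "y", "z")])
    d2 <- colSums((t(mm) - ctr)^2)
    sel <- which(d2 <= spec$radius_mm^2)
    if (!length(sel)) {
      stop("seed '", spec$seeds$name[s], "' has no voxels within ",
           spec$radius_mm, " mm of (", paste(ctr, collapse = ", "), ")")
    }
    for (i in seq_along(maps)) S[i, s] <- mean(maps[[i]]$data[sel])
  }
  v <- .col_vars(S)
  if (any(v <= 0)) {
    stop("seed column(s) with zero variance: ",
         paste(colnames(S)[v <= 0], collapse = ", "))
  }
  S
}

# mm coordinates of every voxel centre for an arbitrary grid/affine
.grid_mm <- function(grid_shape, affine) {
  idx <- as.matrix(expand.grid(i = 0:(grid_shape[1] - 1),
                               j = 0:(grid_shape[2] - 1),
                               k = 0:(grid_shape[3] - 1)))
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

# Masked voxel indices with the seed spheres removed: the PLS voxel block is
# the seed versus the *other* voxels of the brain, so the seed's own voxels
# (which trivially correlate with their own mean) never enter the
# decomposition or the thresholded network.
.seed_excluded_index <- function(mask, spec, affine) {
  masked_idx <- which(as.logical(mask$data))
  mm <- .grid_mm(dim(mask$data), affine)[masked_idx, , drop = FALSE]
  drop <- rep(FALSE, length(masked_idx))
  for (s in seq_len(nrow(spec$seeds))) {
    ctr <- as.numeric(spec$seeds[s, c("x", "y", "z")])
    drop <- drop | colSums((t(mm) - ctr)^2) <= spec$radius_mm^2
  }
  list(keep = !drop, index = masked_idx[!drop])
}

#' Seed-to-voxel between-participant correlation matrix
#'
#' Pearson correlation, across participants, between each seed's mean density
#' and every masked voxel's density.
#'
#' @param seed_matrix participants x seeds matrix.
#' @param maps list of \code{gm_map} (same participant order).
#' @param mask a \code{brain_mask}.
#' @return seeds x voxels correlation matrix, entries in [-1, 1].
#' @export
seed_voxel_correlation <- function(seed_matrix, maps, mask) {
  if (nrow(seed_matrix) < 3) stop("need at least 3 participants")
  X <- cohort_matrix(maps, mask)
  .cross_cor(seed_matrix, X)
}

# columns standardised to mean 0, sd 1; zero-variance columns become zero
.standardize_cols <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sd <- sqrt(pmax(0, (colSums(x^2) - n * mu^2) / (n - 1)))
  z <- sweep(x, 2, mu)
  nz <- sd > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sd[nz], `/`)
  z[, !nz] <- 0
  z
}

.cross_cor <- function(S, X) {
  n <- nrow(S)
  r <- crossprod(.standardize_cols(S), .standardize_cols(X)) / (n - 1)
  pmin(pmax(r, -1), 1)
}

#' Decompose a seed-voxel correlation matrix into latent variables
#'
#' Singular value decomposition of the seeds x voxels matrix; LV k couples a
#' seed salience vector with a whole-brain voxel salience vector, the
#' singular value measuring the cross-block covariance it explains. LVs are
#' ordered by descending singular value; each LV's sign is fixed so that its
#' voxel saliences sum to a non-negative value.
#'
#' @param correlation_matrix seeds x voxels numeric matrix.
#' @return list of latent variables, each a list with \code{index},
#'   \code{singular_value}, \code{seed_salience}, \code{voxel_salience}.
#' @export
decompose <- function(correlation_matrix) {
  R <- as.matrix(correlation_matrix)
  if (!all(is.finite(R))) stop("correlation matrix contains non-finite values")
  sv <- .svd_wide(R)
  lapply(seq_along(sv$d), function(k) {
    u <- sv$u[, k]
    v <- sv$v[, k]
    if (sum(v) < 0) { u <- -u; v <- -v }
    list(index = k, singular_value = sv$d[k],
         seed_salience = u, voxel_salience = v)
  })
}

# SVD of a short-and-wide matrix via the small Gram matrix
.svd_wide <- function(R) {
  m <- nrow(R)
  e <- eigen(tcrossprod(R), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  u <- e$vectors
  v <- crossprod(R, u)
  for (k in seq_len(m)) {
    v[, k] <- if (d[k] > 1e-12) v[, k] / d[k] else 0
  }
  list(d = d, u = u, v = v)
}

.singular_values <- function(R) {
  sqrt(pmax(eigen(tcrossprod(R), symmetric = TRUE, only.values = TRUE)$values, 0))
}

#' Permutation test for latent-variable significance
#'
#' Participant rows of the seed matrix are permuted (sampling without
#' replacement) relative to the voxel data; the correlation + SVD is
#' recomputed per permutation and each LV's p-value is
#' \code{(1 + #(permuted singular value >= observed)) / (n_permutations + 1)}.
#'
#' @param maps template cohort maps.
#' @param spec a \code{seed_spec}.
#' @param mask a \code{brain_mask}.
#' @param n_permutations at least 100; 1000 by default.
#' @param rng_seed integer seed.
#' @param exclude_seeds drop the seed-sphere voxels from the voxel block
#'   (default TRUE; they correlate with their own mean by construction).
#' @return list with \code{perm_p} (per LV), \code{observed} singular values
#'   and the \code{null} matrix of permuted singular values.
#' @export
permutation_test <- function(maps, spec, mask, n_permutations = 1000,
                             rng_seed = 0, exclude_seeds = TRUE) {
  stopifnot(n_permutations >= 100)
  S <- extract_seed_matrix(maps, spec)
  X <- cohort_matrix(maps, mask)
  if (exclude_seeds) {
    keep <- .seed_excluded_index(mask, spec, maps[[1]]$affine)$keep
    X <- X[, keep, drop = FALSE]
  }
  .permutation_test_matrices(S, X, n_permutations, rng_seed)
}

.permutation_test_matrices <- function(S, X, n_permutations, rng_seed) {
  n <- nrow(S)
  Ss <- .standardize_cols(S)
  Zs <- .standardize_cols(X)
  observed <- .singular_values(crossprod(Ss, Zs) / (n - 1))
  k <- length(observed)
  set.seed(rng_seed)
  null <- matrix(NA_real_, n_permutations, k)
  for (p in seq_len(n_permutations)) {
    Sp <- Ss[sample.int(n), , drop = FALSE]
    null[p, ] <- .singular_values(crossprod(Sp, Zs) / (n - 1))
  }
  exceed <- colSums(null >= rep(observed, each = n_permutations))
  list(perm_p = (1 + exceed) / (n_permutations + 1),
       observed = observed, null = null)
}

#' Bootstrap standard errors and bootstrap ratios for an LV's voxel weights
#'
#' Participants are resampled with replacement; the correlation + SVD is
#' recomputed; each bootstrap LV is sign-aligned to the original by the dot
#' product of voxel saliences. The bootstrap ratio (BSR) — each voxel's
#' weight divided by its bootstrap standard error, a voxel reliability
#' statistic — is computed on the unnormalised cross-block projection
#' \code{t(R) \%*\% u} (the voxel salience times the singular value). The
#' unit-norm salience vector is unsuitable for the ratio: its normalisation
#' constraint couples every reliable voxel to the resampling jitter of the
#' whole-brain norm, flooring the ratio at the norm's inverse coefficient of
#' variation and erasing the ranking among reliable voxels. Voxels with
#' standard error below 1e-12 get BSR 0 and are flagged in the
#' \code{degenerate} element.
#'
#' @inheritParams permutation_test
#' @param n_bootstraps at least 100; 1000 by default.
#' @param lv_index which LV to assess (default 1).
#' @return list with \code{bootstrap_se} (projection scale), \code{bsr},
#'   \code{voxel_salience}, \code{projection}, \code{degenerate} (logical),
#'   \code{n_redrawn}.
#' @export
bootstrap_bsr <- function(maps, spec, mask, n_bootstraps = 1000,
                          rng_seed = 0, lv_index = 1, exclude_seeds = TRUE) {
  stopifnot(n_bootstraps >= 100)
  S <- extract_seed_matrix(maps, spec)
  X <- cohort_matrix(maps, mask)
  if (exclude_seeds) {
    keep <- .seed_excluded_index(mask, spec, maps[[1]]$affine)$keep
    X <- X[, keep, drop = FALSE]
  }
  .bootstrap_bsr_matrices(S, X, n_bootstraps, rng_seed, lv_index)
}

.bootstrap_bsr_matrices <- function(S, X, n_bootstraps, rng_seed, lv_index) {
  n <- nrow(S)
  R0 <- .cross_cor(S, X)
  sv0 <- .svd_wide(R0)
  u0 <- sv0$u[, lv_index]
  v0 <- sv0$v[, lv_index]
  if (sum(v0) < 0) { v0 <- -v0; u0 <- -u0 }
  proj0 <- as.numeric(crossprod(R0, u0))   # = singular value * salience
  set.seed(rng_seed)
  acc <- rep(0, ncol(X)); acc2 <- rep(0, ncol(X))
  n_redrawn <- 0L
  attempts_cap <- 10L * n_bootstraps
  b <- 0L; attempts <- 0L
  while (b < n_bootstraps) {
    attempts <- attempts + 1L
    if (attempts > attempts_cap) {
      stop("too many degenerate bootstrap resamples (zero seed variance)")
    }
    idx <- sample.int(n, n, replace = TRUE)
    Sb <- S[idx, , drop = FALSE]
    if (any(.col_vars(Sb) <= 0)) { n_redrawn <- n_redrawn + 1L; next }
    Rb <- .cross_cor(Sb, X[idx, , drop = FALSE])
    svb <- .svd_wide(Rb)
    ub <- svb$u[, lv_index]
    if (sum(svb$v[, lv_index] * v0) < 0) ub <- -ub  # sign-align to original
    pb <- as.numeric(crossprod(Rb, ub))
    acc <- acc + pb
    acc2 <- acc2 + pb^2
    b <- b + 1L
  }
  se <- sqrt(pmax(0, (acc2 - acc^2 / n_bootstraps) / (n_bootstraps - 1)))
  degenerate <- se < 1e-12
  bsr <- ifelse(degenerate, 0, proj0 / se)
  list(bootstrap_se = se, bsr = bsr, voxel_salience = v0,
       projection = proj0, degenerate = degenerate, n_redrawn = n_redrawn)
}

#' Threshold an LV into a sparse covariance-network weight map
#'
#' Retains the \code{ceiling(threshold_fraction * n_masked)} masked voxels
#' with the largest |BSR| (or largest positive BSR when
#' \code{signed = TRUE}), ties broken by ascending voxel index. The retained
#' weight is the LV voxel salience (\code{weight_source = "salience"}, the
#' default) or the BSR itself.
#'
#' @param lv list with \code{voxel_salience} and \code{bsr} over the
#'   analysis voxels (as from \code{bootstrap_bsr}, optionally merged with
#'   \code{decompose} output).
#' @param threshold_fraction fraction in (0, 1); default 0.03 (top 3%).
#' @param voxel_index 1-based linear grid indices the \code{lv} vectors are
#'   defined over (a \code{brain_mask} is also accepted).
#' @param signed retain only positive-BSR voxels before ranking.
#' @param weight_source "salience" or "bsr".
#' @return list with \code{voxel_index} (1-based linear indices into the full
#'   grid), \code{weight}, \code{n_retained}.
#' @export
threshold_network <- function(lv, threshold_fraction = 0.03, voxel_index,
                              signed = FALSE, weight_source = "salience") {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            weight_source %in% c("salience", "bsr"))
  masked_idx <- if (inherits(voxel_index, "brain_mask")) {
    which(as.logical(voxel_index$data))
  } else as.integer(voxel_index)
  bsr <- lv$bsr
  stopifnot(length(bsr) == length(masked_idx))
  n_keep <- ceiling(threshold_fraction * length(masked_idx))
  score <- if (signed) bsr else abs(bsr)
  ord <- order(-score, seq_along(score))
  keep <- sort(ord[seq_len(n_keep)])
  w <- switch(weight_source, salience = lv$voxel_salience, bsr = lv$bsr)
  list(voxel_index = masked_idx[keep], weight = w[keep], n_retained = n_keep)
}

#' Build a structural covariance network model from a template cohort
#'
#' End-to-end seed-PLS: seed extraction, seed-voxel correlation, SVD,
#' permutation significance of LV1, bootstrap ratios, and top-fraction
#' thresholding into a sparse weight map. The template cohort must be
#' disjoint from any cohort later scored or classified with the model.
#'
#' @param template_maps list of \code{gm_map} (template participants only).
#' @param spec a \code{seed_spec}.
#' @param mask a \code{brain_mask}; built from the template maps when NULL.
#' @param n_permutations,n_bootstraps resampling sizes (1000 each by default).
#' @param threshold_fraction retained fraction of masked voxels (0.03).
#' @param rng_seed master seed; the bootstrap stream uses \code{rng_seed + 1}.
#' @param weight_source "salience" (default) or "bsr".
#' @param signed_threshold rank only positive-BSR voxels.
#' @param allow_nonsignificant proceed (with a warning) when LV1's
#'   permutation p exceeds 0.05 instead of refusing.
#' @return object of class \code{scn_model}.
#' @export
build_network <- function(template_maps, spec, mask = NULL,
                          n_permutations = 1000, n_bootstraps = 1000,
                          threshold_fraction = 0.03, rng_seed = 0,
                          weight_source = "salience",
                          signed_threshold = FALSE,
                          allow_nonsignificant = FALSE) {
  if (is.null(mask)) mask <- make_mask(template_maps)
  S <- extract_seed_matrix(template_maps, spec)
  excl <- .seed_excluded_index(mask, spec, template_maps[[1]]$affine)
  X <- cohort_matrix(template_maps, mask)[, excl$keep, drop = FALSE]
  lvs <- decompose(.cross_cor(S, X))
  perm <- .permutation_test_matrices(S, X, n_permutations, rng_seed)
  if (perm$perm_p[1] > 0.05) {
    msg <- sprintf("LV1 is not significant under permutation (p = %.4f)",
                   perm$perm_p[1])
    if (!allow_nonsignificant) {
      stop(msg, "; pass allow_nonsignificant = TRUE to override")
    }
    warning(msg, "; proceeding on override")
  }
  boot <- .bootstrap_bsr_matrices(S, X, n_bootstraps, rng_seed + 1, 1L)
  lv1 <- c(lvs[[1]], list(perm_p = perm$perm_p[1],
                          bsr = boot$bsr, bootstrap_se = boot$bootstrap_se))
  wm <- threshold_network(lv1, threshold_fraction, excl$index,
                          signed = signed_threshold,
                          weight_source = weight_source)
  structure(list(
    seed_spec = spec,
    grid_shape = dim(template_maps[[1]]$data),
    affine = template_maps[[1]]$affine,
    mask_index = excl$index,
    lv = lv1,
    perm_p = perm$perm_p,
    weight_map = wm,
    threshold_fraction = threshold_fraction,
    weight_source = weight_source,
    signed_threshold = signed_threshold,
    n_permutations = n_permutations,
    n_bootstraps = n_bootstraps,
    template_ids = vapply(template_maps, `[[`, "", "participant_id"),
    rng_seed = rng_seed
  ), class = "scn_model")
}

#' @export
print.scn_model <- function(x, ...) {
  cat("<scn_model>", x$seed_spec$network_name, "network |",
      length(x$mask_index), "masked voxels |",
      x$weight_map$n_retained, "retained |",
      sprintf("LV1 perm p = %.4g", x$lv$perm_p), "\n")
  invisible(x)
}

#' Write / read a covariance network model
#'
#' The model is stored as a JSON sidecar (seed spec, thresholds, p-values,
#' sparse weights, rng seed) plus NIfTI volumes of the thresholded weight map
#' and the full BSR map.
#'
#' @param model an \code{scn_model}.
#' @param dir output directory (created if needed).
#' @export
write_network_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- model$grid_shape
  wvol <- array(0, g)
  wvol[model$weight_map$voxel_index] <- model$weight_map$weight
  .write_nifti(wvol, model$affine, file.path(dir, "weight_map.nii.gz"))
  bvol <- array(0, g)
  bvol[model$mask_index] <- model$lv$bsr
  .write_nifti(bvol, model$affine, file.path(dir, "bsr_map.nii.gz"))
  meta <- list(
    network_name = model$seed_spec$network_name,
    seeds = model$seed_spec$seeds,
    radius_mm = model$seed_spec$radius_mm,
    grid_shape = as.integer(model$grid_shape),
    affine = as.numeric(model$affine),
    mask_index = as.integer(model$mask_index),
    singular_value = model$lv$singular_value,
    seed_salience = model$lv$seed_salience,
    perm_p = model$perm_p,
    voxel_index = as.integer(model$weight_map$voxel_index),
    weight = model$weight_map$weight,
    threshold_fraction = model$threshold_fraction,
    weight_source = model$weight_source,
    signed_threshold = model$signed_threshold,
    n_permutations = model$n_permutations,
    n_bootstraps = model$n_bootstraps,
    template_ids = model$template_ids,
    rng_seed = model$rng_seed
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_network_model
#' @export
read_network_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  bsr_img <- RNifti::readNifti(file.path(dir, "bsr_map.nii.gz"))
  mask_index <- as.integer(meta$mask_index)
  structure(list(
    seed_spec = seed_spec(meta$network_name, as.data.frame(meta$seeds),
                          meta$radius_mm),
    grid_shape = as.integer(meta$grid_shape),
    affine = matrix(meta$affine, 4, 4),
    mask_index = mask_index,
    lv = list(index = 1L, singular_value = meta$singular_value,
              seed_salience = meta$seed_salience,
              perm_p = meta$perm_p[1],
              bsr = as.array(bsr_img)[mask_index]),
    perm_p = meta$perm_p,
    weight_map = list(voxel_index = as.integer(meta$voxel_index),
                      weight = meta$weight,
                      n_retained = length(meta$voxel_index)),
    threshold_fraction = meta$threshold_fraction,
    weight_source = meta$weight_source,
    signed_threshold = meta$signed_threshold,
    n_permutations = meta$n_permutations,
    n_bootstraps = meta$n_bootstraps,
    template_ids = meta$template_ids,
    rng_seed = meta$rng_seed
  ), class = "scn_model")
}
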