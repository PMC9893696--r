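#' Project an individual map onto a covariance network model
#'
#' The score map is the voxel-wise product of the individual's grey-matter
#' density and the network weight on the model's retained support; the
#' composite score — the individual's network structural integrity index —
#' is the sum of those products (a sparse dot product).
#'
#' @param map a \code{gm_map} on the model's grid.
#' @param model an \code{scn_model}.
#' @return list of class \code{scn_score}: \code{participant_id},
#'   \code{network_name}, \code{voxel_index}, \code{score} (per retained
#'   voxel), \code{composite_score}.
#' @export
score_map <- function(map, model) {
  if (!identical(dim(map$data), as.integer(model$grid_shape)) ||
      max(abs(map$affine - model$affine)) > 1e-4) {
    stop("map grid/affine does not match the model for participant '",
         map$participant_id, "'")
  }
  s <- map$data[model$weight_map$voxel_index] * model$weight_map$weight
  structure(list(participant_id = map$participant_id,
                 network_name = model$seed_spec$network_name,
                 voxel_index = model$weight_map$voxel_index,
                 score = s,
                 composite_score = sum(s)),
            class = "scn_score")
}

#' Score every participant of a cohort under one model
#'
#' @param maps list of \code{gm_map}.
#' @param model an \code{scn_model}.
#' @return list with \code{scores} (data.frame participant_id, network,
#'   composite_score) and \code{score_matrix} (participants x retained
#'   voxels, columns in ascending voxel index).
#' @export
score_cohort <- function(maps, model) {
  res <- lapply(maps, score_map, model = model)
  m <- do.call(rbind, lapply(res, `[[`, "score"))
  rownames(m) <- vapply(res, `[[`, "", "participant_id")
  colnames(m) <- as.character(model$weight_map$voxel_index)
  list(scores = data.frame(
         participant_id = rownames(m),
         network = model$seed_spec$network_name,
         composite_score = vapply(res, `[[`, 0, "composite_score"),
         stringsAsFactors = FALSE, row.names = NULL),
       score_matrix = m)
}

#' Covariate-adjusted group comparison of composite scores
#'
#' Fits \code{score ~ group + covariates} by least squares and reports the
#' partial F test for the group term, plus raw and covariate-adjusted group
#' means (the latter evaluated at the pooled covariate means).
#'
#' @param scores numeric vector of composite scores, aligned with
#'   \code{cohort} rows.
#' @param cohort phenotype data.frame (see \code{\link{read_phenotypes}}).
#' @param contrast character pair of group labels, e.g. \code{c("sNC","pNC")}.
#' @param covariates column names used as nuisance covariates; default
#'   \code{c("age", "sex", "education", "tiv")}. Extra categorical columns
#'   (scanner site, field strength, ...) may be added freely.
#' @return list of class \code{scn_ancova}: \code{contrast},
#'   \code{covariates}, \code{F_statistic}, \code{p_value}, \code{df},
#'   \code{group_means} (raw mean, sd, n), \code{adjusted_means}.
#' @export
ancova_compare <- function(scores, cohort,
                           contrast = c("sNC", "pNC"),
                           covariates = c("age", "sex", "education", "tiv")) {
  stopifnot(length(contrast) == 2, length(scores) == nrow(cohort))
  sel <- cohort$group %in% contrast
  if (!all(contrast %in% cohort$group)) {
    stop("contrast group(s) absent from the cohort: ",
         paste(setdiff(contrast, cohort$group), collapse = ", "))
  }
  d <- cohort[sel, , drop = FALSE]
  d$.score <- scores[sel]
  d$group <- factor(d$group, levels = contrast)
  for (cv in covariates) {
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  }
  rhs <- paste(c("group", covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(".score ~", rhs)), data = d)
  if (anyNA(stats::coef(full))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "))
  }
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  reduced <- stats::lm(stats::as.formula(paste(".score ~", rhs0)), data = d)
  an <- stats::anova(reduced, full)
  Fv <- an$F[2]
  pv <- an$`Pr(>F)`[2]

  newdata <- d[1:2, , drop = FALSE]
  newdata$group <- factor(contrast, levels = contrast)
  for (cv in covariates) {
    newdata[[cv]] <- if (is.numeric(d[[cv]])) rep(mean(d[[cv]]), 2)
                     else factor(rep(levels(d[[cv]])[1], 2), levels(d[[cv]]))
  }
  adj <- stats::predict(full, newdata = newdata)
  raw <- do.call(rbind, lapply(contrast, function(g) {
    x <- d$.score[d$group == g]
    data.frame(group = g, mean = mean(x), sd = stats::sd(x), n = length(x))
  }))
  structure(list(contrast = contrast, covariates = covariates,
                 F_statistic = Fv, p_value = pv,
                 df = c(an$Df[2], an$Res.Df[2]),
                 group_means = raw,
                 adjusted_means = stats::setNames(as.numeric(adj), contrast)),
            class = "scn_ancova")
}

#' @export
print.scn_ancova <- function(x, ...) {
  cat(sprintf("<scn_ancova> %s vs %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$contrast[1], x$contrast[2], x$df[1], x$df[2],
              x$F_statistic, x$p_value))
  invisible(x)
}

#' Pearson correlation between composite scores and a regional density
#'
#' @param scores numeric vector (e.g. composite network scores).
#' @param region_densities numeric vector of the same length (e.g. mean
#'   hippocampal density per participant).
#' @return list with \code{r}, \code{p_value} (two-sided), \code{n}.
#' @export
score_density_correlation <- function(scores, region_densities) {
  stopifnot(length(scores) == length(region_densities))
  if (length(scores) < 3) stop("need at least 3 pairs")
  if (stats::sd(scores) == 0 || stats::sd(region_densities) == 0) {
    stop("zero variance in scores or densities")
  }
  ct <- stats::cor.test(scores, region_densities, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(scores))
}
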