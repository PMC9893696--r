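#' Binary transition labels for a prediction contrast
#'
#' @param cohort phenotype data.frame.
#' @param contrast length-2 character; the second label is the positive
#'   (transition) class, e.g. \code{c("sNC", "pNC")} or
#'   \code{c("non-rMCI", "rMCI")}.
#' @return factor over the selected rows plus an attribute \code{rows} giving
#'   the cohort row indices used.
#' @export
transition_labels <- function(cohort, contrast) {
  stopifnot(length(contrast) == 2)
  rows <- which(cohort$group %in% contrast)
  if (length(unique(cohort$group[rows])) < 2) {
    stop("both contrast groups must be present: ",
         paste(contrast, collapse = " vs "))
  }
  structure(factor(cohort$group[rows], levels = contrast), rows = rows)
}

#' Feature table from covariance-network score maps
#'
#' One column per retained model voxel (density x weight), columns in
#' ascending voxel index; rows are participants.
#'
#' @param scored result of \code{\link{score_cohort}}.
#' @param model the \code{scn_model} used to score.
#' @param labels binary factor aligned with rows (see
#'   \code{\link{transition_labels}}); may be NULL for unlabelled use.
#' @return list of class \code{feature_table}: \code{x}, \code{feature_ids},
#'   \code{labels}, \code{feature_kind = "voxel"}.
#' @export
build_features_from_scores <- function(scored, model, labels = NULL) {
  ids <- model$weight_map$voxel_index
  if (!identical(as.integer(colnames(scored$score_matrix)), as.integer(ids))) {
    stop("score matrix support does not match the model's retained voxels")
  }
  .feature_table(scored$score_matrix, ids, labels, "voxel")
}

#' Feature table of mean atlas-region densities
#'
#' @param maps list of \code{gm_map}.
#' @param atlas an \code{atlas_volume}.
#' @param region_ids integer atlas region ids.
#' @param labels optional binary factor aligned with \code{maps}.
#' @export
build_features_from_regions <- function(maps, atlas, region_ids,
                                        labels = NULL) {
  x <- t(vapply(maps, region_mean_density, numeric(length(region_ids)),
                atlas = atlas, region_ids = region_ids))
  if (length(region_ids) == 1L) x <- matrix(x, ncol = 1L)
  rownames(x) <- vapply(maps, `[[`, "", "participant_id")
  zv <- .col_vars(x) <= 0
  if (any(zv)) {
    message("zero-variance region feature(s): ",
            paste(region_ids[zv], collapse = ", "))
  }
  .feature_table(x, region_ids, labels, "region")
}

.feature_table <- function(x, feature_ids, labels, kind) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature table contains missing values")
  if (!is.null(labels)) {
    labels <- factor(labels)
    stopifnot(length(labels) == nrow(x))
    if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  }
  structure(list(x = x, feature_ids = feature_ids, labels = labels,
                 feature_kind = kind),
            class = "feature_table")
}

#' Receiver operating characteristic curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a positive scores above a
#' negative, with ties counted one half; the curve is swept over the sorted
#' unique scores as thresholds (predict positive when score >= threshold).
#'
#' @param labels binary factor (second level positive) or logical vector.
#' @param scores numeric predicted scores/probabilities.
#' @return list with \code{roc_points} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
compute_roc <- function(labels, scores) {
  pos <- if (is.logical(labels)) labels else {
    labels <- factor(labels)
    if (nlevels(labels) != 2) stop("labels must have exactly two classes")
    labels == levels(labels)[2]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # midranks: ties count one half
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & pos), 0)
  fp <- vapply(thr, function(t) sum(scores >= t & !pos), 0)
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / n0),
                    tpr = c(0, tp / n1))
  list(roc_points = roc, auc = auc)
}

# stratified fold assignment: within each class, a random permutation is
# dealt out cyclically over folds
.stratified_folds <- function(y, n_folds, rng_seed) {
  set.seed(rng_seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < n_folds) {
      stop("class '", lev, "' has fewer members (", length(idx),
           ") than folds (", n_folds, "); use a larger cohort or fewer folds")
    }
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated random-forest prediction of clinical transition
#'
#' Stratified k-fold cross-validation of a probability random forest.
#' Per-fold AUC is computed on held-out predictions; the pooled out-of-fold
#' probabilities define the reported ROC curve, with sensitivity and
#' specificity taken at the pooled-curve point maximising Youden's J
#' (sensitivity + specificity - 1).
#'
#' @param features a \code{feature_table} with labels.
#' @param n_folds folds (default 5).
#' @param n_trees trees per forest (default 500).
#' @param rng_seed integer; fixes folds and forests, so reports are
#'   reproducible byte for byte.
#' @param importance "impurity" (default, Gini) or "permutation".
#' @param mtry features per split; default floor(sqrt(p)).
#' @return list of class \code{prediction_report}: \code{auc_mean},
#'   \code{auc_sd}, \code{fold_auc}, \code{pooled_auc}, \code{sensitivity},
#'   \code{specificity}, \code{youden_threshold}, \code{roc_points},
#'   \code{oof_prob}, \code{fold}, \code{fold_importance}, \code{n_folds},
#'   \code{n_trees}, \code{rng_seed}, \code{positive_class}.
#' @export
cross_validated_rf <- function(features, n_folds = 5, n_trees = 500,
                               rng_seed = 0, importance = "impurity",
                               mtry = NULL) {
  stopifnot(inherits(features, "feature_table"), !is.null(features$labels),
            importance %in% c("impurity", "permutation"))
  x <- features$x
  y <- features$labels
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fold <- .stratified_folds(y, n_folds, rng_seed)
  pos_level <- levels(y)[2]
  oof <- rep(NA_real_, length(y))
  fold_auc <- numeric(n_folds)
  fold_imp <- matrix(0, ncol(x), n_folds)
  dat <- data.frame(x, check.names = FALSE)
  colnames(dat) <- paste0("f", seq_len(ncol(x)))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2) stop("training split lost a class")
    fit <- ranger::ranger(x = dat[tr, , drop = FALSE], y = y[tr],
                          num.trees = n_trees, mtry = min(mtry, ncol(x)),
                          probability = TRUE, importance = importance,
                          seed = rng_seed + k, num.threads = 1)
    pr <- stats::predict(fit, data = dat[!tr, , drop = FALSE],
                         num.threads = 1)$predictions[, pos_level]
    oof[!tr] <- pr
    fold_auc[k] <- compute_roc(y[!tr], pr)$auc
    fold_imp[, k] <- fit$variable.importance
  }
  pooled <- compute_roc(y, oof)
  j <- pooled$roc_points$tpr - pooled$roc_points$fpr
  best <- which.max(j)
  structure(list(
    auc_mean = mean(fold_auc), auc_sd = stats::sd(fold_auc),
    fold_auc = fold_auc, pooled_auc = pooled$auc,
    sensitivity = pooled$roc_points$tpr[best],
    specificity = 1 - pooled$roc_points$fpr[best],
    youden_threshold = pooled$roc_points$threshold[best],
    roc_points = pooled$roc_points,
    oof_prob = oof, fold = fold,
    fold_importance = fold_imp,
    feature_ids = features$feature_ids,
    feature_kind = features$feature_kind,
    n_folds = n_folds, n_trees = n_trees, rng_seed = rng_seed,
    positive_class = pos_level
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "<prediction_report> AUC %.3f (+/- %.3f) over %d folds | SEN %.3f SPE %.3f\n",
    x$auc_mean, x$auc_sd, x$n_folds, x$sensitivity, x$specificity))
  invisible(x)
}

#' Feature-importance distribution of a cross-validated forest
#'
#' Per-fold importances are averaged across folds, floored at zero
#' (permutation importance can dip below), and renormalised to sum to 1.
#' When every importance is zero the distribution falls back to uniform.
#'
#' @param report a \code{prediction_report}.
#' @return named numeric vector summing to 1 (names = feature ids).
#' @export
importance_map <- function(report) {
  imp <- pmax(rowMeans(report$fold_importance), 0)
  if (sum(imp) == 0) imp <- rep(1, length(imp))
  stats::setNames(imp / sum(imp), as.character(report$feature_ids))
}

#' Render voxel-feature importances onto the model grid
#'
#' @param importance vector from \code{\link{importance_map}} of a voxel
#'   (score-map) model.
#' @param model the \code{scn_model} defining the voxel support.
#' @return 3-D array with importances at retained voxels, 0 elsewhere.
#' @export
importance_volume <- function(importance, model) {
  vol <- array(0, model$grid_shape)
  vol[as.integer(names(importance))] <- importance
  vol
}

#' Rank atlas regions by summed voxel-feature importance
#'
#' @param importance vector from \code{\link{importance_map}} (voxel mode).
#' @param atlas an \code{atlas_volume} on the model grid.
#' @param top_n number of regions to report (default 10).
#' @return data.frame(region_id, region_name, importance), descending.
#' @export
aggregate_importance <- function(importance, atlas, top_n = 10) {
  vox <- as.integer(names(importance))
  region <- as.integer(atlas$data[vox])
  keep <- region > 0
  agg <- tapply(importance[keep], region[keep], sum)
  out <- data.frame(region_id = as.integer(names(agg)),
                    region_name = unname(atlas$labels[names(agg)]),
                    importance = as.numeric(agg))
  out <- out[order(-out$importance), , drop = FALSE]
  utils::head(out, top_n)
}
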