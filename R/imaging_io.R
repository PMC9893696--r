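#' Grey-matter density map
#'
#' Container for one participant's voxel-wise grey-matter density volume,
#' together with the 4x4 affine that maps 0-based voxel indices to MNI
#' millimetre coordinates.
#'
#' @param data 3-D numeric array of grey-matter density (fractions in [0,1]).
#' @param affine 4x4 numeric matrix; \code{mm = affine \%*\% c(i, j, k, 1)}
#'   with 0-based voxel indices.
#' @param participant_id character scalar.
#' @param clamp clamp densities into [0,1] (values outside by more than 1e-6
#'   are an error when \code{clamp = FALSE}).
#' @return An object of class \code{gm_map}.
#' @export
gm_map <- function(data, affine, participant_id, clamp = TRUE) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (!all(is.finite(data))) {
    stop("non-finite density values for participant '", participant_id, "'")
  }
  if (clamp) {
    data[] <- pmin(pmax(data, 0), 1)
  } else if (min(data) < -1e-6 || max(data) > 1 + 1e-6) {
    stop("densities outside [0,1] for participant '", participant_id, "'")
  }
  structure(
    list(data = data, affine = affine, participant_id = as.character(participant_id)),
    class = "gm_map"
  )
}

#' @export
print.gm_map <- function(x, ...) {
  cat("<gm_map> participant", x$participant_id,
      "| grid", paste(dim(x$data), collapse = "x"),
      "| density range", sprintf("[%.3f, %.3f]", min(x$data), max(x$data)), "\n")
  invisible(x)
}

#' Read / write grey-matter density maps as NIfTI-1
#'
#' @param path file path (.nii or .nii.gz).
#' @param participant_id id to attach; defaults to the file stem.
#' @return \code{read_gm_map}: a \code{gm_map}; \code{write_gm_map}: the path,
#'   invisibly.
#' @export
read_gm_map <- function(path, participant_id = NULL) {
  img <- RNifti::readNifti(path)
  aff <- .rnifti_affine(img)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  gm_map(array(as.numeric(img), dim = dim(img)), aff, participant_id)
}

#' @rdname read_gm_map
#' @param map a \code{gm_map}.
#' @export
write_gm_map <- function(map, path) {
  .write_nifti(map$data, map$affine, path)
  invisible(path)
}

# RNifti stores the voxel->mm transform for 1-based R indices internally; we
# standardise on the NIfTI convention (0-based) throughout.
.rnifti_affine <- function(img) {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  matrix(as.numeric(aff), 4, 4)
}

.write_nifti <- function(data, affine, path, datatype = "double") {
  img <- RNifti::asNifti(data, datatype = datatype)
  img$sform_code <- 2L
  img$qform_code <- 0L
  img$srow_x <- affine[1, ]
  img$srow_y <- affine[2, ]
  img$srow_z <- affine[3, ]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a CSV/TSV with header columns \code{participant_id, group, age,
#' sex, education, tiv} and optionally \code{apoe4}. Group labels must be
#' drawn from \code{sNC, pNC, non-rMCI, rMCI}; sex from \code{M, F}.
#'
#' @param path CSV or TSV file.
#' @return data.frame (one row per participant).
#' @export
read_phenotypes <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_cohort(tab)
}

#' @rdname read_phenotypes
#' @param cohort a candidate cohort data.frame.
#' @export
validate_cohort <- function(cohort) {
  required <- c("participant_id", "group", "age", "sex", "education", "tiv")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("phenotype table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cohort$participant_id)) {
    stop("duplicate participant_id: ",
         paste(unique(cohort$participant_id[duplicated(cohort$participant_id)]),
               collapse = ", "))
  }
  bad <- setdiff(unique(cohort$group), c("sNC", "pNC", "non-rMCI", "rMCI"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  if (!all(cohort$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (is.null(cohort$apoe4)) cohort$apoe4 <- "unknown"
  cohort
}

#' Load a cohort of density maps plus phenotypes
#'
#' All images must share one grid and affine; every image must have a matching
#' phenotype row (matched on participant id = file stem). Maps are returned in
#' phenotype-row order.
#'
#' @param image_paths character vector of NIfTI paths.
#' @param phenotype_path CSV/TSV phenotype table.
#' @return list with elements \code{maps} (list of \code{gm_map}) and
#'   \code{cohort} (data.frame, rows aligned with \code{maps}).
#' @export
load_cohort <- function(image_paths, phenotype_path) {
  maps <- lapply(image_paths, read_gm_map)
  ids <- vapply(maps, `[[`, "", "participant_id")
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m$data), dim(ref$data))) {
      stop("grid shape mismatch for participant '", m$participant_id, "'")
    }
    if (max(abs(m$affine - ref$affine)) > 1e-4) {
      stop("affine mismatch for participant '", m$participant_id, "'")
    }
  }
  cohort <- read_phenotypes(phenotype_path)
  unmatched <- setdiff(ids, cohort$participant_id)
  if (length(unmatched)) {
    stop("no phenotype row for image(s): ", paste(unmatched, collapse = ", "))
  }
  cohort <- cohort[cohort$participant_id %in% ids, , drop = FALSE]
  maps <- maps[match(cohort$participant_id, ids)]
  list(maps = maps, cohort = cohort)
}

#' Convert between MNI millimetre coordinates and voxel indices
#'
#' Voxel indices are 0-based. \code{mni_to_voxel} rounds to the nearest voxel,
#' breaking half-way ties toward negative infinity, and errors when the
#' coordinate falls outside the grid.
#'
#' @param coord MNI mm coordinate, length-3 numeric.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param grid_shape optional length-3 integer grid dimensions for the
#'   in-grid check.
#' @param label name used in the out-of-grid error message.
#' @return length-3 integer (0-based) voxel index.
#' @export
mni_to_voxel <- function(coord, affine, grid_shape = NULL, label = "coordinate") {
  v <- solve(affine, c(coord, 1))[1:3]
  idx <- as.integer(ceiling(v - 0.5))  # nearest, ties toward -Inf
  if (!is.null(grid_shape) && (any(idx < 0L) || any(idx >= grid_shape))) {
    stop(label, " at MNI (", paste(coord, collapse = ", "),
         ") falls outside the image grid")
  }
  idx
}

#' @rdname mni_to_voxel
#' @param idx 0-based voxel index triple.
#' @export
voxel_to_mni <- function(idx, affine) {
  (affine %*% c(idx, 1))[1:3]
}

#' Build the analysis mask
#'
#' A voxel enters the mask when its mean density across participants exceeds
#' \code{density_threshold} and its cross-participant variance is strictly
#' positive (so Pearson correlation is always defined).
#'
#' @param maps list of \code{gm_map} on one grid (at least 2).
#' @param density_threshold mean-density cutoff, default 0.2 (the usual
#'   voxel-based-morphometry convention).
#' @return object of class \code{brain_mask}: logical array + affine +
#'   \code{n_voxels}.
#' @export
make_mask <- function(maps, density_threshold = 0.2) {
  stopifnot(length(maps) >= 2)
  x <- cohort_matrix(maps)
  mu <- colMeans(x)
  v <- .col_vars(x)
  keep <- mu > density_threshold & v > 0
  if (!any(keep)) stop("analysis mask is empty (threshold too high or degenerate maps)")
  data <- array(keep, dim = dim(maps[[1]]$data))
  structure(list(data = data, affine = maps[[1]]$affine,
                 n_voxels = sum(keep)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask>", x$n_voxels, "of", length(x$data), "voxels\n")
  invisible(x)
}

#' Flatten a cohort to a participants-by-voxels matrix
#'
#' @param maps list of \code{gm_map}.
#' @param mask optional \code{brain_mask}; when given, columns are restricted
#'   to masked voxels (in ascending linear voxel index order).
#' @return numeric matrix, rows in cohort order.
#' @export
cohort_matrix <- function(maps, mask = NULL) {
  x <- do.call(rbind, lapply(maps, function(m) as.numeric(m$data)))
  rownames(x) <- vapply(maps, `[[`, "", "participant_id")
  if (!is.null(mask)) x <- x[, as.logical(mask$data), drop = FALSE]
  x
}

.col_vars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' Atlas volume with region labels
#'
#' @param data 3-D integer array, 0 = background.
#' @param labels named character vector or data.frame(id, name) mapping region
#'   ids to names.
#' @param affine 4x4 affine.
#' @return object of class \code{atlas_volume}.
#' @export
atlas_volume <- function(data, labels, affine) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$name), labels$id)
  }
  ids <- sort(unique(as.integer(data[data != 0])))
  missing <- setdiff(ids, as.integer(names(labels)))
  if (length(missing)) {
    stop("atlas contains unlabelled region id(s): ", paste(missing, collapse = ", "))
  }
  structure(list(data = data, labels = labels, affine = affine),
            class = "atlas_volume")
}

#' Read an atlas (NIfTI volume + two-column TSV of id, name)
#' @param volume_path NIfTI integer label volume.
#' @param labels_path TSV with columns \code{id} and \code{name}.
#' @export
read_atlas <- function(volume_path, labels_path) {
  img <- RNifti::readNifti(volume_path)
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  atlas_volume(array(as.integer(img), dim = dim(img)), lab, .rnifti_affine(img))
}

#' @rdname read_atlas
#' @param atlas an \code{atlas_volume}.
#' @export
write_atlas <- function(atlas, volume_path, labels_path) {
  .write_nifti(atlas$data, atlas$affine, volume_path, datatype = "int16")
  utils::write.table(
    data.frame(id = names(atlas$labels), name = unname(atlas$labels)),
    labels_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(volume_path)
}

#' Mean grey-matter density per atlas region
#'
#' @param map a \code{gm_map}.
#' @param atlas an \code{atlas_volume} on the same grid.
#' @param region_ids integer region ids (must be present in the atlas).
#' @return named numeric vector of unweighted in-region means.
#' @export
region_mean_density <- function(map, atlas, region_ids) {
  stopifnot(identical(dim(map$data), dim(atlas$data)))
  out <- vapply(region_ids, function(id) {
    sel <- atlas$data == id
    if (!any(sel)) stop("atlas region ", id, " contains no voxels")
    mean(map$data[sel])
  }, numeric(1))
  names(out) <- atlas$labels[as.character(region_ids)]
  out
}
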