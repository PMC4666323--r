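#' Voxel grid: image shape plus voxel-to-mm affine
#'
#' Voxel indices are 0-based internally; millimetre coordinates are obtained
#' through the affine as `mm = A %*% c(i, j, k, 1)`.
#'
#' @param shape Integer length-3 image dimensions.
#' @param affine 4 x 4 voxel-index-to-mm matrix (must be invertible). If
#'   `NULL`, a diagonal affine is built from `spacing` and `origin`.
#' @param spacing Voxel size in mm per axis (used when `affine` is `NULL`);
#'   the default matches a 3.3 x 3.3 x 3 mm EPI acquisition.
#' @param origin mm coordinate of voxel (0, 0, 0).
#' @return An object of class `voxel_grid`.
#' @examples
#' grid <- voxel_grid(c(64, 64, 47))
#' @export
voxel_grid <- function(shape, affine = NULL,
                       spacing = c(3.3, 3.3, 3), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) abort("`affine` must be invertible.")
  structure(list(shape = shape, affine = affine), class = "voxel_grid")
}

# mm coordinates of the centers of the given 0-based voxel indices (n x 3)
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

# continuous 0-based voxel coordinates of mm points (n x 3)
mm_to_voxel <- function(grid, mm) {
  mm <- matrix(mm, ncol = 3)
  t(solve(grid$affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
}

# 0-based ijk of every voxel, in ascending linear-index order
all_voxel_indices <- function(grid) {
  as.matrix(expand.grid(i = 0:(grid$shape[1] - 1),
                        j = 0:(grid$shape[2] - 1),
                        k = 0:(grid$shape[3] - 1)))
}

# snap an mm center to the nearest voxel center; errors if it rounds outside
# the grid
snap_center <- function(center, grid) {
  idx <- round(mm_to_voxel(grid, center))
  if (any(idx < 0) || any(idx >= matrix(grid$shape, 1))) {
    abort(sprintf(
      "ROI center (%s mm) snaps to voxel (%s), outside the %s grid.",
      paste(center, collapse = ", "), paste(idx, collapse = ", "),
      paste(grid$shape, collapse = " x ")))
  }
  drop(voxel_to_mm(grid, idx))
}

#' Build a spherical ROI mask
#'
#' The requested mm center is snapped to the nearest voxel center; the mask
#' contains exactly the voxels whose center lies within `radius` mm
#' (Euclidean) of the snapped center.
#'
#' @param center Length-3 mm coordinates.
#' @param radius Sphere radius in mm (> 0).
#' @param grid A [voxel_grid()].
#' @return 3-D logical array of dimension `grid$shape`.
#' @examples
#' grid <- voxel_grid(c(20, 20, 20))
#' sum(build_sphere_mask(c(33, 33, 30), 8, grid))
#' @export
build_sphere_mask <- function(center, radius, grid) {
  if (!all(is.finite(center)) || length(center) != 3) {
    abort("`center` must be 3 finite mm coordinates.")
  }
  if (radius <= 0) abort("`radius` must be > 0.")
  ctr <- snap_center(center, grid)
  mm <- voxel_to_mm(grid, all_voxel_indices(grid))
  d2 <- (mm[, 1] - ctr[1])^2 + (mm[, 2] - ctr[2])^2 + (mm[, 3] - ctr[3])^2
  mask <- array(d2 <= radius^2, dim = grid$shape)
  if (!any(mask)) abort("Sphere contains no voxel of the grid.")
  mask
}

#' Build a cubic ROI mask
#'
#' Axis-aligned in mm space: a voxel belongs to the mask when its center
#' satisfies `|delta| <= edge / 2` on every mm axis relative to the snapped
#' center.
#'
#' @param center Length-3 mm coordinates.
#' @param edge Cube edge length in mm (> 0).
#' @param grid A [voxel_grid()].
#' @return 3-D logical array of dimension `grid$shape`.
#' @export
build_cube_mask <- function(center, edge, grid) {
  if (!all(is.finite(center)) || length(center) != 3) {
    abort("`center` must be 3 finite mm coordinates.")
  }
  if (edge <= 0) abort("`edge` must be > 0.")
  ctr <- snap_center(center, grid)
  mm <- voxel_to_mm(grid, all_voxel_indices(grid))
  ok <- abs(mm[, 1] - ctr[1]) <= edge / 2 &
    abs(mm[, 2] - ctr[2]) <= edge / 2 &
    abs(mm[, 3] - ctr[3]) <= edge / 2
  mask <- array(ok, dim = grid$shape)
  if (!any(mask)) abort("Cube contains no voxel of the grid.")
  mask
}

#' Describe an ROI by name, hemisphere and geometric definition
#'
#' Exactly one of `mask_file`, `sphere` or `cube` must be given. Coordinates
#' are interpreted in the space of the grid they are later applied to; no
#' template-space conversion is performed (`space_label` is carried as
#' metadata only).
#'
#' @param name ROI label.
#' @param hemisphere `"L"`, `"R"` or `"none"`.
#' @param mask_file Path to a NIfTI mask.
#' @param sphere `list(center = c(x, y, z), radius = r)` in mm.
#' @param cube `list(center = c(x, y, z), edge = e)` in mm.
#' @param space_label Free-text coordinate-space tag (e.g. `"MNI"`).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, hemisphere = c("none", "L", "R"),
                     mask_file = NULL, sphere = NULL, cube = NULL,
                     space_label = "") {
  hemisphere <- match.arg(hemisphere)
  ndef <- sum(!is.null(mask_file), !is.null(sphere), !is.null(cube))
  if (ndef != 1) {
    abort("Exactly one of `mask_file`, `sphere`, `cube` must be supplied.")
  }
  if (!is.null(sphere) && (is.null(sphere$radius) || sphere$radius <= 0)) {
    abort("`sphere$radius` must be > 0.")
  }
  if (!is.null(cube) && (is.null(cube$edge) || cube$edge <= 0)) {
    abort("`cube$edge` must be > 0.")
  }
  structure(list(name = name, hemisphere = hemisphere,
                 mask_file = mask_file, sphere = sphere, cube = cube,
                 space_label = space_label),
            class = "roi_spec")
}

#' Realize an ROI specification as a mask on a grid
#'
#' @param spec An [roi_spec()].
#' @param grid A [voxel_grid()] (ignored for `mask_file` definitions, whose
#'   grid is read from the file).
#' @return 3-D logical array.
#' @export
build_roi_mask <- function(spec, grid) {
  if (!is.null(spec$mask_file)) {
    img <- RNifti::readNifti(spec$mask_file)
    return(array(as.array(img) != 0, dim = dim(img)))
  }
  if (!is.null(spec$sphere)) {
    return(build_sphere_mask(spec$sphere$center, spec$sphere$radius, grid))
  }
  build_cube_mask(spec$cube$center, spec$cube$edge, grid)
}

#' Extract an ROI's voxel time series from a 4-D image
#'
#' Voxels are taken in ascending linear-index order (the order of
#' `which(mask)`), giving a deterministic, documented column order.
#'
#' @param image4d 4-D numeric array (x, y, z, time) or an `RNifti` image.
#' @param mask 3-D logical/0-1 array matching the image's spatial grid.
#' @param run_labels Integer run label per volume.
#' @param tr Repetition time (s).
#' @param roi,subject,hemisphere Labels attached to the result.
#' @return An [roi_ts()] of dimension time x `sum(mask)`.
#' @export
extract_roi_timeseries <- function(image4d, mask, run_labels, tr = 3,
                                   roi = "roi", subject = "sub-01",
                                   hemisphere = "none") {
  img <- as.array(image4d)
  if (length(dim(img)) != 4) abort("`image4d` must be 4-dimensional.")
  if (!all(dim(img)[1:3] == dim(mask))) {
    abort(sprintf("Mask grid (%s) does not match image grid (%s).",
                  paste(dim(mask), collapse = " x "),
                  paste(dim(img)[1:3], collapse = " x ")))
  }
  if (length(run_labels) != dim(img)[4]) {
    abort("`run_labels` must have one entry per volume.")
  }
  vox <- which(mask != 0)
  if (!length(vox)) abort("Empty ROI mask.")
  n_t <- dim(img)[4]
  flat <- matrix(img, ncol = n_t)  # voxel x time
  roi_ts(t(flat[vox, , drop = FALSE]), run = run_labels, tr = tr,
         roi = roi, subject = subject, hemisphere = hemisphere)
}

#' Write and read masks / 4-D images as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} fixing the voxel-to-mm affine from a
#' [voxel_grid()]. Masks round-trip bit-exactly as integers.
#'
#' @param mask 3-D logical/integer array.
#' @param grid A [voxel_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly (writers); an array (readers).
#' @export
write_mask_nifti <- function(mask, grid, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param image4d 4-D numeric array (x, y, z, time).
#' @param tr Repetition time stored in the header (s).
#' @export
write_image_nifti <- function(image4d, grid, path, tr = 3) {
  img <- RNifti::asNifti(image4d)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.array(img) != 0, dim = dim(img))
}

#' @rdname write_mask_nifti
#' @export
read_image_nifti <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Pack ROI time series into a 4-D image for end-to-end tests
#'
#' Places the columns of an [roi_ts()] at the masked voxels of an otherwise
#' zero 4-D array, inverting [extract_roi_timeseries()].
#'
#' @param ts An [roi_ts()].
#' @param mask 3-D logical array with `sum(mask) == ncol(ts$data)`.
#' @return 4-D array of dimension `c(dim(mask), nrow(ts$data))`.
#' @export
embed_roi_timeseries <- function(ts, mask) {
  vox <- which(mask != 0)
  if (length(vox) != ncol(ts$data)) {
    abort("`mask` voxel count must equal the number of columns of `ts`.")
  }
  n_t <- nrow(ts$data)
  img <- array(0, dim = c(dim(mask), n_t))
  flat <- matrix(img, ncol = n_t)
  flat[vox, ] <- t(ts$data)
  array(flat, dim = c(dim(mask), n_t))
}
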