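# Containers for statistic maps and brain masks, the default analysis grid,
# and small spatial utilities (NIfTI round-trip, separable Gaussian smoothing).

#' Construct a statistic map
#'
#' A `stat_map` bundles a 3D array of voxelwise statistic values (z or t
#' scale), a 4x4 voxel-to-world affine in millimetres, and a free-form
#' metadata list (typically one manifest record).
#'
#' @param data numeric 3D array.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @param meta named list of metadata.
#' @return an object of class `stat_map`.
#' @export
stat_map <- function(data, affine = default_affine(dim(data)), meta = list()) {
  if (length(dim(data)) != 3L) stopf("'data' must be a 3D array")
  if (!is.matrix(affine) || any(dim(affine) != 4L)) stopf("'affine' must be a 4x4 matrix")
  structure(list(data = data, affine = affine, meta = meta), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<stat_map> %d x %d x %d, values in [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  if (!is.null(x$meta$image_id)) cat("  image_id:", x$meta$image_id, "\n")
  invisible(x)
}

#' Construct a brain mask
#'
#' @param data logical 3D array; `TRUE` marks in-brain voxels.
#' @param affine 4x4 voxel-to-world transform (mm).
#' @return an object of class `brain_mask`.
#' @export
brain_mask <- function(data, affine = default_affine(dim(data))) {
  if (length(dim(data)) != 3L) stopf("mask 'data' must be a 3D array")
  storage.mode(data) <- "logical"
  if (!any(data)) stopf("brain mask is empty")
  structure(list(data = data, affine = affine), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_mask> %d x %d x %d, %d in-mask voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' Default analysis grid
#'
#' The common grid all maps are resampled to: 48 x 56 x 48 voxels at 4 mm
#' isotropic spacing, centred on the MNI152 field of view.
#' @return integer vector of length 3.
#' @export
default_grid <- function() c(48L, 56L, 48L)

#' Default voxel-to-world affine for a grid
#'
#' Diagonal 4 mm affine centring the grid on the origin, the convention used
#' for all synthetic data. 0-based voxel indices map to mm coordinates.
#'
#' @param shape grid shape (length-3 integer).
#' @param spacing voxel size in mm.
#' @return 4x4 matrix.
#' @export
default_affine <- function(shape = default_grid(), spacing = 4) {
  a <- diag(c(rep(spacing, 3), 1))
  a[1:3, 4] <- -(shape - 1) / 2 * spacing
  a
}

#' Ellipsoid brain mask
#'
#' Synthetic stand-in for a template brain mask when no real mask file is
#' supplied: the ellipsoid inscribed in the grid, shrunk by a small margin.
#'
#' @param shape grid shape.
#' @param affine voxel-to-world transform.
#' @param margin shrinkage of each semi-axis, in voxels.
#' @return a [brain_mask].
#' @export
ellipsoid_mask <- function(shape = default_grid(), affine = default_affine(shape),
                           margin = 2) {
  ctr <- (shape - 1) / 2
  semi <- pmax(shape / 2 - margin, 1)
  d1 <- ((seq_len(shape[1]) - 1 - ctr[1]) / semi[1])^2
  d2 <- ((seq_len(shape[2]) - 1 - ctr[2]) / semi[2])^2
  d3 <- ((seq_len(shape[3]) - 1 - ctr[3]) / semi[3])^2
  m <- outer(outer(d1, d2, `+`), d3, `+`) <= 1
  brain_mask(m, affine)
}

#' Load a brain mask from a NIfTI file
#'
#' Values strictly above 0.5 are treated as in-mask.
#' @param path NIfTI file.
#' @return a [brain_mask].
#' @export
read_brain_mask <- function(path) {
  img <- RNifti::readNifti(path)
  brain_mask(array(as.numeric(img) > 0.5, dim = dim(img)), affine_of(img))
}

#' Read a statistic map from a NIfTI-1 file
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param meta optional metadata list attached to the map.
#' @return a [stat_map].
#' @export
read_stat_map <- function(path, meta = list()) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) > 3L) dm <- dm[1:3]
  stat_map(array(as.numeric(img)[seq_len(prod(dm))], dim = dm), affine_of(img), meta)
}

#' Write a statistic map as NIfTI-1
#'
#' @param map a [stat_map].
#' @param path output path (.nii.gz recommended).
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  img <- RNifti::asNifti(map$data)
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

affine_of <- function(img) {
  x <- RNifti::xform(img)
  matrix(as.numeric(x), 4, 4, dimnames = NULL)
}

# Separable Gaussian smoothing on the voxel grid. `fwhm` in mm, `spacing`
# the voxel size in mm. Kernels are renormalised at the borders.
gaussian_smooth3 <- function(arr, fwhm, spacing = 4) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / spacing  # voxels
  sm_axis <- function(a, axis) {
    n <- dim(a)[axis]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    m <- K %*% matrix(aperm(a, perm), n)
    aperm(array(m, dim(a)[perm]), order(perm))
  }
  sm_axis(sm_axis(sm_axis(arr, 1), 2), 3)
}
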