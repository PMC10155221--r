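# Preprocessing: bring any statistic map onto the common analysis grid with
# normalised in-brain values. The pipeline order is resample -> min-max
# normalise -> mask; the min/max support is restricted to in-mask voxels so
# that background zeros never dominate the value range.

#' Resample a statistic map onto a target grid
#'
#' Trilinear interpolation in world (mm) space: each target voxel centre is
#' mapped through the target affine and back through the inverse of the
#' source affine. Non-finite source voxels are replaced by 0 before
#' interpolation, and points falling outside the source grid evaluate to 0.
#'
#' @param map a [stat_map].
#' @param target_shape voxel grid of the output.
#' @param target_affine 4x4 voxel-to-world transform of the output.
#' @return a [stat_map] on the target grid.
#' @export
resample_to_grid <- function(map, target_shape = default_grid(),
                             target_affine = default_affine(target_shape)) {
  if (any(target_shape < 1)) stopf("'target_shape' must be positive")
  if (abs(det(map$affine)) < 1e-12) stopf("source affine is singular")
  src <- map$data
  src[!is.finite(src)] <- 0
  sdim <- dim(src)
  # identity resample: already on the target grid
  if (identical(as.integer(sdim), as.integer(target_shape)) &&
      max(abs(map$affine - target_affine)) < 1e-9) {
    return(stat_map(src, target_affine, map$meta))
  }

  # 0-based target voxel indices -> world -> 0-based source voxel coords
  g <- as.matrix(expand.grid(i = seq_len(target_shape[1]) - 1,
                             j = seq_len(target_shape[2]) - 1,
                             k = seq_len(target_shape[3]) - 1))
  xf <- solve(map$affine) %*% target_affine
  vox <- cbind(g, 1) %*% t(xf[1:3, , drop = FALSE])

  f <- floor(vox)
  w <- vox - f
  # gather with 0 outside the source grid (1-based corner indices)
  val_at <- function(ci, cj, ck) {
    ok <- ci >= 1 & ci <= sdim[1] & cj >= 1 & cj <= sdim[2] & ck >= 1 & ck <= sdim[3]
    out <- numeric(nrow(vox))
    if (any(ok)) {
      lin <- ci[ok] + sdim[1] * (cj[ok] - 1) + sdim[1] * sdim[2] * (ck[ok] - 1)
      out[ok] <- src[lin]
    }
    out
  }
  i0 <- f[, 1] + 1; j0 <- f[, 2] + 1; k0 <- f[, 3] + 1
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  vals <-
    val_at(i0,     j0,     k0)     * (1 - wx) * (1 - wy) * (1 - wz) +
    val_at(i0 + 1, j0,     k0)     * wx       * (1 - wy) * (1 - wz) +
    val_at(i0,     j0 + 1, k0)     * (1 - wx) * wy       * (1 - wz) +
    val_at(i0 + 1, j0 + 1, k0)     * wx       * wy       * (1 - wz) +
    val_at(i0,     j0,     k0 + 1) * (1 - wx) * (1 - wy) * wz +
    val_at(i0 + 1, j0,     k0 + 1) * wx       * (1 - wy) * wz +
    val_at(i0,     j0 + 1, k0 + 1) * (1 - wx) * wy       * wz +
    val_at(i0 + 1, j0 + 1, k0 + 1) * wx       * wy       * wz
  stat_map(array(vals, target_shape), target_affine, map$meta)
}

#' Min-max normalise a statistic map to \[-1, 1\]
#'
#' With `m` and `M` the minimum and maximum over in-mask voxels, values are
#' mapped by `x -> 2 * (x - m) / (M - m) - 1`, so the in-mask minimum maps
#' to -1 and the maximum to +1. A constant map maps to all zeros in-mask. A
#' sign-preserving alternative `x -> x / max(|x|)` is available as method
#' `"symmetric"`.
#'
#' @param map a [stat_map] on the target grid.
#' @param mask a [brain_mask] on the same grid.
#' @param method `"minmax"` (default) or `"symmetric"`.
#' @return a [stat_map] with values in \[-1, 1\].
#' @export
minmax_normalize <- function(map, mask, method = c("minmax", "symmetric")) {
  method <- match.arg(method)
  check_same_grid(map, mask)
  v <- map$data[mask$data]
  out <- map$data
  if (method == "minmax") {
    m <- min(v); M <- max(v)
    if (M == m) {
      out[] <- 0
    } else {
      out <- 2 * (out - m) / (M - m) - 1
    }
  } else {
    s <- max(abs(v))
    if (s == 0) out[] <- 0 else out <- out / s
    out <- pmin(pmax(out, -1), 1)
  }
  stat_map(out, map$affine, map$meta)
}

#' Zero all out-of-mask voxels of a map
#'
#' @param map a [stat_map].
#' @param mask a [brain_mask] on the same grid.
#' @return a [stat_map]; in-mask voxels are unchanged.
#' @export
apply_brain_mask <- function(map, mask) {
  check_same_grid(map, mask)
  out <- map$data
  out[!mask$data] <- 0
  stat_map(out, map$affine, map$meta)
}

check_same_grid <- function(map, mask) {
  if (!inherits(mask, "brain_mask")) stopf("'mask' must be a brain_mask")
  if (!any(mask$data)) stopf("brain mask is empty")
  if (!identical(dim(map$data), dim(mask$data)))
    stopf("map grid %s does not match mask grid %s",
          paste(dim(map$data), collapse = "x"),
          paste(dim(mask$data), collapse = "x"))
  invisible(TRUE)
}

#' Full preprocessing pipeline for one map
#'
#' Resample to the target grid, min-max normalise over in-mask voxels, then
#' zero everything outside the brain mask. The pipeline is idempotent on
#' its own output.
#'
#' @param map a [stat_map].
#' @param mask a [brain_mask] on the target grid.
#' @param target_shape,target_affine the analysis grid.
#' @param method normalisation method, see [minmax_normalize].
#' @return a preprocessed [stat_map].
#' @export
preprocess_map <- function(map, mask,
                           target_shape = dim(mask$data),
                           target_affine = mask$affine,
                           method = "minmax") {
  res <- resample_to_grid(map, target_shape, target_affine)
  apply_brain_mask(minmax_normalize(res, mask, method), mask)
}
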