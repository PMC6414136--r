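#' Resample a volume or mask to isotropic spacing
#'
#' Resamples onto an isotropic lattice that shares the center of voxel
#' (1,1,1) with the input (the origin is unchanged). Scalar volumes are
#' interpolated trilinearly; masks use nearest-neighbour sampling so they
#' stay binary. The physical extent (first to last voxel center) is preserved
#' to within one target voxel.
#'
#' Clinical head protocols are anisotropic (e.g. 3 mm slices over sub-mm
#' in-plane pixels); shell construction and the QA metrics assume
#' near-isotropic voxels, so volumes are normally brought to the working
#' resolution (1 mm by default elsewhere) before any morphology.
#'
#' @param x A [ct_volume()] or [binary_mask()].
#' @param target_spacing_mm Positive scalar, the isotropic voxel size in mm.
#' @return An object of the same class as `x` on the new lattice.
#' @export
resample_isotropic <- function(x, target_spacing_mm) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "binary_mask"))
  if (!is.numeric(target_spacing_mm) || length(target_spacing_mm) != 1L ||
      !is.finite(target_spacing_mm) || target_spacing_mm <= 0) {
    stop("target_spacing_mm must be a positive number")
  }
  if (max(abs(x$spacing - target_spacing_mm)) < 1e-9) return(x)
  d <- dim(x$voxels)
  extent <- (d - 1L) * x$spacing
  newdim <- pmax(1L, as.integer(round(extent / target_spacing_mm)) + 1L)
  is_mask <- inherits(x, "binary_mask")
  vox <- if (is_mask) array(as.double(x$voxels), dim = d) else x$voxels
  out <- cpp_resample(as.vector(vox), d, x$spacing, newdim,
                      rep(target_spacing_mm, 3), nearest = is_mask)
  out <- array(out, dim = newdim)
  if (is_mask) {
    binary_mask(out > 0.5, rep(target_spacing_mm, 3), x$origin, x$axes)
  } else {
    ct_volume(out, rep(target_spacing_mm, 3), x$origin, x$axes)
  }
}
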