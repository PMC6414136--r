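#' Write a volume or mask to a NIfTI container
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) is used as the package's self-describing
#' volume container: it stores the grid, spacing, origin and direction
#' cosines in one file and round-trips exactly. Masks are stored as 0/1
#' integer grids. NIfTI's spatial frame is RAS+, so the LPS patient-frame
#' affine is sign-flipped on the first two rows when writing and flipped back
#' when reading; coordinates reported by this package are always LPS mm.
#'
#' @param x A [ct_volume()] or [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "binary_mask"))
  arr <- x$voxels
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim = dim(arr))
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  flip <- diag(c(-1, -1, 1))
  lin <- flip %*% (x$axes %*% diag(x$spacing))
  aff <- rbind(cbind(lin, flip %*% x$origin), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume or mask from a NIfTI container
#'
#' @param path Path to a `.nii`/`.nii.gz` file written by [write_volume()]
#'   (or any NIfTI-1 volume with a valid spatial transform).
#' @param mask If `TRUE`, interpret voxels > 0.5 as a [binary_mask()];
#'   otherwise return a [ct_volume()] of HU values.
#' @return A `ct_volume` or `binary_mask`.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
  flip <- diag(c(-1, -1, 1))
  lin <- flip %*% aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  axes <- lin %*% diag(1 / spacing)
  origin <- as.numeric(flip %*% aff[1:3, 4])
  if (mask) {
    binary_mask(array(arr > 0.5, dim = dim(arr)), spacing, origin, axes)
  } else {
    ct_volume(array(as.double(arr), dim = dim(arr)), spacing, origin, axes)
  }
}
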