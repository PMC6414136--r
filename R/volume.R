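#' CT volume on a regular grid
#'
#' Container for a 3D scalar grid of Hounsfield units (HU) with its geometry
#' in the patient frame. The patient frame is the DICOM LPS convention
#' (+x left, +y posterior, +z superior); all physical quantities in this
#' package (origins, spacings, meshes, gaps, thicknesses) are millimetres in
#' that frame. Voxel indices address voxel centers: voxel `(i, j, k)`
#' (1-based in R) sits at `origin + axes %*% ((c(i,j,k) - 1) * spacing)`.
#'
#' @param voxels 3D numeric array of HU values in `[-1024, 3071]`.
#' @param spacing Per-axis voxel size in mm (length 1 or 3, all > 0).
#' @param origin Patient-frame position (mm) of the center of voxel (1,1,1).
#' @param axes 3x3 matrix of direction cosines (columns are the patient-frame
#'   directions of the grid axes); must be orthonormal to 1e-6.
#' @return An object of class `ct_volume`.
#' @seealso [binary_mask()], [read_ct_series()], [write_volume()]
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), axes = diag(3)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  storage.mode(voxels) <- "double"
  geom <- .check_geometry(spacing, origin, axes)
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071) {
    stop("HU values must lie within [-1024, 3071]; observed range [",
         rng[1], ", ", rng[2], "]")
  }
  structure(
    list(voxels = voxels, spacing = geom$spacing, origin = geom$origin,
         axes = geom$axes),
    class = "ct_volume"
  )
}

#' Binary mask sharing a CT volume's grid
#'
#' A boolean grid with the same geometry semantics as [ct_volume()]: masks
#' produced from a volume live on the identical lattice (no half-voxel
#' shifts), so distance-transform geometry is unambiguous.
#'
#' @param voxels 3D logical array.
#' @inheritParams ct_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0), axes = diag(3)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L, is.logical(voxels))
  geom <- .check_geometry(spacing, origin, axes)
  structure(
    list(voxels = voxels, spacing = geom$spacing, origin = geom$origin,
         axes = geom$axes),
    class = "binary_mask"
  )
}

.check_geometry <- function(spacing, origin, axes) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("all spacing components must be positive")
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  axes <- as.matrix(axes)
  stopifnot(all(dim(axes) == c(3L, 3L)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6) {
    stop("grid axes must be orthonormal (tolerance 1e-6)")
  }
  list(spacing = spacing, origin = origin, axes = axes)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, HU range [%g, %g]\n",
              paste(signif(x$origin, 5), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing %s mm, %d set\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              sum(x$voxels)))
  invisible(x)
}

#' Test whether two grids share the same geometry
#'
#' @param a,b `ct_volume` or `binary_mask` objects.
#' @param tol Numeric tolerance on spacing/origin/axes (mm).
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$axes - b$axes)) <= tol
}

.stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b)) stop("input grids do not share the same geometry")
  invisible(TRUE)
}

# Mask inheriting geometry from a template volume/mask.
mask_like <- function(template, voxels) {
  binary_mask(voxels, template$spacing, template$origin, template$axes)
}

# Patient-frame coordinate (single component `axis_row`) of every voxel
# center, returned as an array matching the grid. Exploits separability:
# coord = origin[m] + sum_q axes[m, q] * spacing[q] * (idx_q - 1).
.coord_component <- function(x, axis_row = 3L) {
  d <- dim(x$voxels)
  cx <- x$axes[axis_row, 1] * x$spacing[1] * (seq_len(d[1]) - 1)
  cy <- x$axes[axis_row, 2] * x$spacing[2] * (seq_len(d[2]) - 1)
  cz <- x$axes[axis_row, 3] * x$spacing[3] * (seq_len(d[3]) - 1)
  x$origin[axis_row] + outer(outer(cx, cy, "+"), cz, "+")
}

# Exact Euclidean distance (mm) from each voxel center to the nearest TRUE
# voxel center of `mask` (0 on TRUE voxels, Inf if the mask is empty).
mask_distance_mm <- function(mask) {
  d <- cpp_edt(as.logical(mask$voxels), dim(mask$voxels), mask$spacing)
  array(d, dim = dim(mask$voxels))
}

# 6-neighbourhood erosion/dilation by one voxel via array shifts.
.shift_logical <- function(a, delta) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (m in 1:3) {
    if (delta[m] >= 0) {
      src[[m]] <- seq_len(d[m] - delta[m])
      dst[[m]] <- seq_len(d[m] - delta[m]) + delta[m]
    } else {
      src[[m]] <- seq_len(d[m] + delta[m]) - delta[m]
      dst[[m]] <- seq_len(d[m] + delta[m])
    }
    if (length(src[[m]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

.erode6 <- function(a) {
  out <- a
  for (m in 1:3) {
    for (s in c(-1L, 1L)) {
      delta <- integer(3L)
      delta[m] <- s
      out <- out & .shift_logical(a, delta)
    }
  }
  out
}

.dilate6 <- function(a) {
  out <- a
  for (m in 1:3) {
    for (s in c(-1L, 1L)) {
      delta <- integer(3L)
      delta[m] <- s
      out <- out | .shift_logical(a, delta)
    }
  }
  out
}

# Surface voxels: TRUE voxels with at least one FALSE 6-neighbour (grid
# boundary counts as outside).
.surface_voxels <- function(a) {
  inner <- .erode6(a)
  # voxels on the grid boundary are never "inner"
  d <- dim(a)
  inner[c(1, d[1]), , ] <- FALSE
  inner[, c(1, d[2]), ] <- FALSE
  inner[, , c(1, d[3])] <- FALSE
  a & !inner
}
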