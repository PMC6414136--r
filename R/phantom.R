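#' Specification of a synthetic head phantom
#'
#' Describes an analytic "head": an ellipsoid of soft-tissue HU containing a
#' concentric bone shell, surrounded by air, voxelized on a regular isotropic
#' grid. Because the outer surface is a quadric, surface position, cap
#' volumes and shell thickness all have closed-form ground truth, which makes
#' every downstream stage (segmentation, shell construction, meshing, QA
#' metrics) testable without any scan data.
#'
#' The skull shell is bounded by the concentric ellipsoids with semi-axes
#' `head_radii - scalp_mm` and `head_radii - scalp_mm - bone_shell_mm`.
#' For a spherical head (`all equal head_radii`), optional low-amplitude
#' sinusoidal surface bumps exercise conformality on a non-convex scalp:
#' the surface radius becomes
#' `R + bump_amplitude_mm * sin(bump_cycles * theta) * cos(bump_cycles * phi)`
#' in spherical coordinates.
#'
#' @param head_radii Semi-axes of the head ellipsoid in mm (length 1 or 3).
#'   The default, `c(75, 95, 85)`, approximates an adult cranium
#'   (width x length x height).
#' @param tissue_hu Soft-tissue HU (default 40).
#' @param bone_hu Skull-shell HU (default 700).
#' @param air_hu Background HU (default -1000).
#' @param bone_shell_mm Skull shell thickness in mm (default 6).
#' @param scalp_mm Soft-tissue depth between skin and skull outer surface,
#'   mm (default 6).
#' @param noise_sd_hu SD of additive Gaussian HU noise (default 0; >= 0).
#' @param seed Integer seed for the noise generator.
#' @param spacing_mm Isotropic voxel size of the generated grid (default 1).
#' @param margin_mm Air margin between the head surface and the grid boundary
#'   (default 15, must be >= 10 so that dilation never touches the grid).
#' @param bump_amplitude_mm,bump_cycles Optional scalp bumps (spheres only).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(head_radii = c(75, 95, 85), tissue_hu = 40,
                         bone_hu = 700, air_hu = -1000, bone_shell_mm = 6,
                         scalp_mm = 6, noise_sd_hu = 0, seed = 1L,
                         spacing_mm = 1, margin_mm = 15,
                         bump_amplitude_mm = 0, bump_cycles = 6) {
  head_radii <- as.numeric(head_radii)
  if (length(head_radii) == 1L) head_radii <- rep(head_radii, 3L)
  stopifnot(length(head_radii) == 3L, all(head_radii > 0),
            spacing_mm > 0, noise_sd_hu >= 0, bone_shell_mm > 0,
            scalp_mm > 0, bump_amplitude_mm >= 0)
  if (margin_mm < 10) stop("margin_mm must be at least 10 mm")
  if (min(head_radii) - scalp_mm - bone_shell_mm <= 0) {
    stop("scalp_mm + bone_shell_mm must be smaller than the smallest radius")
  }
  if (bump_amplitude_mm > 0 && length(unique(head_radii)) != 1L) {
    stop("surface bumps are only supported on spherical heads")
  }
  structure(
    list(head_radii = head_radii, tissue_hu = tissue_hu, bone_hu = bone_hu,
         air_hu = air_hu, bone_shell_mm = bone_shell_mm, scalp_mm = scalp_mm,
         noise_sd_hu = noise_sd_hu, seed = as.integer(seed),
         spacing_mm = spacing_mm, margin_mm = margin_mm,
         bump_amplitude_mm = bump_amplitude_mm, bump_cycles = bump_cycles),
    class = "phantom_spec"
  )
}

#' Generate a synthetic head CT with analytic ground truth
#'
#' Voxelizes the phantom described by a [phantom_spec()]: each voxel center is
#' classified as air, soft tissue, or bone by closed-form ellipsoid
#' membership, then seeded Gaussian noise is added and HU are clipped to
#' `[-1024, 3071]`. Generation is a pure function of the spec (including the
#' seed): the caller's RNG state is saved and restored.
#'
#' The grid is centered on the head: the voxel lattice is symmetric about the
#' patient-frame origin, so the analytic surface is centered at `c(0, 0, 0)`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a [ct_volume()]) and `surface` (a
#'   `phantom_surface` supporting exact signed point-to-surface distance
#'   queries via [surface_distance()]).
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  half_n <- ceiling((spec$head_radii + spec$margin_mm) / sp)
  d <- 2L * as.integer(half_n) + 1L
  origin <- -(d - 1L) / 2 * sp
  xs <- origin[1] + (seq_len(d[1]) - 1L) * sp
  ys <- origin[2] + (seq_len(d[2]) - 1L) * sp
  zs <- origin[3] + (seq_len(d[3]) - 1L) * sp

  rho2 <- function(radii) {
    outer(outer((xs / radii[1])^2, (ys / radii[2])^2, "+"), (zs / radii[3])^2,
          "+")
  }

  if (spec$bump_amplitude_mm > 0) {
    R <- spec$head_radii[1]
    r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
    r <- sqrt(r2)
    zarr <- outer(outer(rep(0, d[1]), rep(0, d[2]), "+"), zs, "+")
    yarr <- outer(outer(rep(0, d[1]), ys, "+"), rep(0, d[3]), "+")
    xarr <- outer(outer(xs, rep(0, d[2]), "+"), rep(0, d[3]), "+")
    theta <- acos(pmin(pmax(ifelse(r > 0, zarr / r, 1), -1), 1))
    phi <- atan2(yarr, xarr)
    r_eff <- R + spec$bump_amplitude_mm * sin(spec$bump_cycles * theta) *
      cos(spec$bump_cycles * phi)
    head <- r <= r_eff
  } else {
    head <- rho2(spec$head_radii) <= 1
  }
  skull_outer <- rho2(spec$head_radii - spec$scalp_mm) <= 1
  skull_inner <- rho2(spec$head_radii - spec$scalp_mm - spec$bone_shell_mm) <= 1

  hu <- array(spec$air_hu, dim = d)
  hu[head] <- spec$tissue_hu
  hu[skull_outer & !skull_inner] <- spec$bone_hu

  if (spec$noise_sd_hu > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(spec$seed)
    hu <- hu + rnorm(length(hu), sd = spec$noise_sd_hu)
  }
  hu <- pmin(pmax(hu, -1024), 3071)

  surface <- structure(
    list(kind = if (spec$bump_amplitude_mm > 0) "bumpy_sphere" else "ellipsoid",
         radii = spec$head_radii, center = c(0, 0, 0),
         bump_amplitude_mm = spec$bump_amplitude_mm,
         bump_cycles = spec$bump_cycles),
    class = "phantom_surface"
  )
  list(volume = ct_volume(array(hu, dim = d), sp, origin), surface = surface)
}

#' Signed distance from points to a phantom surface
#'
#' Negative inside the head, positive outside, in mm. Exact for ellipsoids
#' (Newton/bisection on the standard point-to-ellipsoid root equation); for
#' bumpy spheres the distance is the radial first-order approximation
#' `|p| - r_eff(direction)`, accurate to O(amplitude x cycles / R).
#'
#' @param surface A `phantom_surface` from [generate_head_phantom()].
#' @param points Numeric matrix (n x 3) of patient-frame coordinates in mm.
#' @return Numeric vector of n signed distances in mm.
#' @export
surface_distance <- function(surface, points) {
  stopifnot(inherits(surface, "phantom_surface"))
  points <- rbind(points)
  pts <- sweep(points, 2L, surface$center)
  if (surface$kind == "bumpy_sphere") {
    r <- sqrt(rowSums(pts^2))
    theta <- acos(pmin(pmax(ifelse(r > 0, pts[, 3] / r, 1), -1), 1))
    phi <- atan2(pts[, 2], pts[, 1])
    r_eff <- surface$radii[1] + surface$bump_amplitude_mm *
      sin(surface$bump_cycles * theta) * cos(surface$bump_cycles * phi)
    return(r - r_eff)
  }
  a <- surface$radii
  if (length(unique(a)) == 1L) {
    return(sqrt(rowSums(pts^2)) - a[1])
  }
  vapply(seq_len(nrow(pts)), function(q) {
    .ellipsoid_distance(pts[q, ], a)
  }, 0)
}

# Signed Euclidean distance from a point to an axis-aligned ellipsoid with
# semi-axes a, centered at the origin. Solves sum((a_i p_i / (a_i^2 + t))^2)
# = 1 for t by bisection; the closest surface point is x_i = a_i^2 p_i /
# (a_i^2 + t).
.ellipsoid_distance <- function(p, a) {
  inside <- sum((p / a)^2) <= 1
  if (all(abs(p) < 1e-12)) return(-min(a))
  # nudge exactly-zero components so the root bracket below is valid; the
  # induced distance error is O(1e-9) mm
  p <- ifelse(abs(p) < 1e-9, 1e-9, p)
  g <- function(t) sum((a * p / (a^2 + t))^2) - 1
  lo <- -min(a)^2 * (1 - 1e-12)
  # expand upper bracket until g(hi) < 0
  hi <- max(sum(abs(a * p)), 1)
  while (g(hi) > 0) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(1, abs(hi))) break
  }
  t <- (lo + hi) / 2
  x <- a^2 * p / (a^2 + t)
  dist <- sqrt(sum((p - x)^2))
  if (inside) -dist else dist
}

#' Translate a mask by the nearest whole-voxel offset
#'
#' Shifts the TRUE voxels of a mask by `round(offset_mm / spacing)` voxels
#' along each grid axis. Used to construct masks with known air gaps for QA
#' metric verification. Errors if any TRUE voxel would be pushed off the
#' grid (the shift would otherwise silently truncate the mask).
#'
#' @param mask A [binary_mask()].
#' @param offset_mm Numeric length-3 offset in mm along the grid axes.
#' @return The shifted [binary_mask()].
#' @export
shift_mask <- function(mask, offset_mm) {
  stopifnot(inherits(mask, "binary_mask"), length(offset_mm) == 3L)
  dv <- as.integer(round(offset_mm / mask$spacing))
  if (all(dv == 0L)) return(mask)
  a <- mask$voxels
  d <- dim(a)
  idx <- which(a, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    new_idx <- sweep(idx, 2L, dv, "+")
    if (any(new_idx < 1L) || any(new_idx > rep(d, each = nrow(new_idx)))) {
      stop("shift would truncate the mask at the grid boundary")
    }
  }
  out <- .shift_logical(a, dv)
  mask_like(mask, out)
}
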