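#' Triangle mesh in patient coordinates
#'
#' @param vertices Numeric matrix (n x 3), mm, patient (LPS) frame.
#' @param faces Integer matrix (m x 3) of 1-based vertex indices with
#'   consistent outward winding.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L,
            min(faces) >= 1L, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, volume %.1f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Divergence theorem over signed tetrahedra to the origin; positive for a
#' watertight mesh with outward winding.
#' @param mesh A [triangle_mesh()].
#' @return Numeric scalar, mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Surface area of a mesh (mm^2)
#' @param mesh A [triangle_mesh()].
#' @return Numeric scalar, mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  n <- .face_normals(mesh, normalize = FALSE)
  sum(sqrt(rowSums(n^2))) / 2
}

.face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' Check that a mesh is watertight with positive enclosed volume
#'
#' A mesh passes when every undirected edge is shared by exactly two faces
#' with opposite direction (closed, consistently oriented 2-manifold), no
#' face is degenerate, and the enclosed volume is positive.
#'
#' @param mesh A [triangle_mesh()].
#' @param area_tol Faces with area below this (mm^2) count as degenerate.
#' @return `TRUE`/`FALSE` for [is_watertight()]; [validate_mesh()] errors
#'   with the reason and returns the mesh invisibly.
#' @export
is_watertight <- function(mesh, area_tol = 1e-9) {
  ok <- tryCatch({
    validate_mesh(mesh, area_tol)
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' @rdname is_watertight
#' @export
validate_mesh <- function(mesh, area_tol = 1e-9) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  n <- .face_normals(mesh, normalize = FALSE)
  areas <- sqrt(rowSums(n^2)) / 2
  if (any(areas <= area_tol)) {
    stop(sum(areas <= area_tol), " degenerate faces (area <= ", area_tol, ")")
  }
  audit <- cpp_edge_audit(mesh$faces, nrow(mesh$vertices))
  if (audit$duplicated > 0L || audit$unmatched > 0L) {
    stop("mesh is not a closed, consistently oriented 2-manifold (",
         audit$unmatched, " unmatched and ", audit$duplicated,
         " duplicated directed edges)")
  }
  vol <- mesh_volume(mesh)
  if (vol <= 0) stop("mesh encloses non-positive volume (", vol, " mm^3)")
  invisible(mesh)
}

#' Extract a watertight surface mesh from a binary mask
#'
#' Extracts the 0.5 iso-surface of the (optionally Gaussian pre-smoothed)
#' mask indicator with marching tetrahedra on the Kuhn cell decomposition,
#' which triangulates shared cell faces identically in neighbouring cells and
#' therefore yields a watertight surface by construction. The mask is padded
#' with one layer of background before extraction so surfaces touching the
#' grid boundary still close. Vertices are reported in mm in the patient
#' frame.
#'
#' @param mask A nonempty, single-component [binary_mask()].
#' @param smooth_sigma_vox Optional Gaussian pre-smoothing of the indicator
#'   field, in voxels (default 0 = none; 0.5 gives slightly rounder
#'   surfaces at sub-voxel cost to fidelity).
#' @return A [triangle_mesh()].
#' @export
mask_to_mesh <- function(mask, smooth_sigma_vox = 0) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("empty mask: nothing to mesh")
  lab <- cpp_label6(as.logical(mask$voxels), dim(mask$voxels))
  ncomp <- attr(lab, "n_components")
  if (ncomp > 1L) {
    stop("mask has ", ncomp, " connected components; mesh one at a time")
  }
  d <- dim(mask$voxels)
  field <- array(0, dim = d + 2L)
  field[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <-
    as.double(mask$voxels)
  if (smooth_sigma_vox > 0) {
    field <- array(cpp_gauss3(as.vector(field), dim(field), smooth_sigma_vox),
                   dim = dim(field))
  }
  mc <- cpp_marching_tets(as.vector(field), dim(field), mask$spacing, 0.5)
  # undo the one-voxel pad, then map grid-frame mm to the patient frame
  vg <- sweep(mc$vertices, 2L, mask$spacing)
  vp <- vg %*% t(mask$axes)
  vp <- sweep(vp, 2L, mask$origin, "+")
  mesh <- triangle_mesh(vp, mc$faces)
  validate_mesh(mesh)
  mesh
}

#' Smooth a mesh while bounding vertex displacement
#'
#' Taubin lambda/mu smoothing (a low-pass filter that avoids the shrinkage of
#' plain Laplacian smoothing), followed by a hard clamp of each vertex's
#' total displacement to `max_deviation_mm`. Topology is untouched, so
#' watertightness is preserved.
#'
#' @param mesh A watertight [triangle_mesh()].
#' @param iterations Number of lambda/mu passes (default 10; 0 returns the
#'   mesh unchanged).
#' @param max_deviation_mm Upper bound on any vertex's displacement from its
#'   input position, mm (default 0.5, half a typical working voxel).
#' @param lambda,mu Taubin filter coefficients.
#' @return The smoothed [triangle_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 10L, max_deviation_mm = 0.5,
                        lambda = 0.5, mu = -0.53) {
  stopifnot(inherits(mesh, "triangle_mesh"), iterations >= 0,
            max_deviation_mm >= 0)
  if (iterations == 0L) return(mesh)
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  edges <- unique(edges)
  deg <- tabulate(edges[, 1], nbins = nrow(mesh$vertices))
  v0 <- mesh$vertices
  v <- v0
  for (it in seq_len(iterations)) {
    for (w in c(lambda, mu)) {
      nb_mean <- rowsum(v[edges[, 2], , drop = FALSE], edges[, 1],
                        reorder = TRUE) / deg
      v <- v + w * (nb_mean - v)
    }
  }
  disp <- v - v0
  dlen <- sqrt(rowSums(disp^2))
  scale <- ifelse(dlen > max_deviation_mm, max_deviation_mm / dlen, 1)
  triangle_mesh(v0 + disp * scale, f)
}

#' Write a mesh as binary STL
#'
#' Binary little-endian STL: 80-byte header, 32-bit facet count, then 50
#' bytes per facet (normal, three vertices as 32-bit floats, 2-byte
#' attribute). Facet normals are recomputed from the winding. Units are mm
#' in the patient (LPS) frame; no coordinate flip is applied. Output is
#' deterministic (no timestamps), so identical meshes give byte-identical
#' files.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  nf <- nrow(f)
  normals <- .face_normals(mesh, normalize = TRUE)
  rec <- cbind(normals, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  flt <- writeBin(as.vector(t(rec)), raw(), size = 4L, endian = "little")
  body <- rbind(matrix(flt, nrow = 48L), matrix(as.raw(0), nrow = 2L,
                                                ncol = nf))
  header <- charToRaw(sprintf("%-80s", "binary STL; units mm; LPS frame"))
  header <- header[1:80]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  writeBin(as.vector(body), con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Validates that the file length equals `84 + 50 * facet_count` and welds
#' exactly coincident vertices so downstream watertightness checks work on
#' the result.
#'
#' @param path Path to a binary STL file.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 84L) stop("not a binary STL: file shorter than 84 bytes")
  nf <- readBin(r[81:84], integer(), size = 4L, endian = "little")
  if (nf < 0) stop("facet count overflows a signed 32-bit integer")
  expected <- 84 + 50 * as.numeric(nf)
  if (length(r) != expected) {
    stop("file length ", length(r), " does not match 84 + 50 x ", nf,
         " = ", expected, " bytes (truncated or ASCII STL?)")
  }
  if (nf == 0L) stop("STL contains no facets")
  recs <- matrix(r[-(1:84)], nrow = 50L)
  flt <- readBin(as.vector(recs[1:48, ]), numeric(), n = 12L * nf, size = 4L,
                 endian = "little")
  m <- matrix(flt, ncol = 12L, byrow = TRUE)
  verts <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                 m[, 10:12, drop = FALSE])
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  first <- !duplicated(key)
  map <- match(key, key[first])
  faces <- matrix(map, ncol = 3L)
  triangle_mesh(verts[first, , drop = FALSE], faces)
}

#' Voxelize a closed mesh onto a reference grid
#'
#' Parity ray casting along the first grid axis: voxel centers inside the
#' mesh become TRUE. The inverse of [mask_to_mesh()] up to surface
#' discretization; used by the QA entry point when the bolus is supplied as
#' an STL file rather than a mask.
#'
#' @param mesh A watertight [triangle_mesh()] in the patient frame.
#' @param template A [ct_volume()] or [binary_mask()] defining the target
#'   grid.
#' @return A [binary_mask()] on `template`'s grid.
#' @export
voxelize_mesh <- function(mesh, template) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  vg <- sweep(mesh$vertices, 2L, template$origin) %*% template$axes
  d <- dim(template$voxels)
  vox <- cpp_voxelize(vg, mesh$faces, d, template$spacing)
  mask_like(template, array(vox, dim = d))
}
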