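# Shared analytic fixtures. Masks are built directly from closed-form
# geometry so tests have exact ground truth independent of the package's own
# segmentation and phantom code.

# Radial distance of every voxel center from the patient-frame origin, for a
# grid centered on the origin.
radial_grid <- function(dims, spacing) {
  ax <- lapply(1:3, function(m) {
    (seq_len(dims[m]) - 1 - (dims[m] - 1) / 2) * spacing[m]
  })
  sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
}

# Sphere mask of radius r mm, grid centered on the origin.
sphere_mask <- function(r, spacing = 1, margin = 12) {
  spacing <- rep(spacing, length.out = 3)
  dims <- 2L * as.integer(ceiling((r + margin) / spacing)) + 1L
  rr <- radial_grid(dims, spacing)
  binary_mask(rr <= r, spacing,
              origin = -(dims - 1) / 2 * spacing)
}

# Small spherical test phantom (noise free) shared by several tests.
small_sphere_phantom <- function(r = 30, spacing = 1) {
  generate_head_phantom(phantom_spec(head_radii = r, spacing_mm = spacing,
                                     scalp_mm = 5, bone_shell_mm = 5,
                                     margin_mm = 12))
}

# Full-grid extent mask on a template's geometry.
full_extent <- function(template) {
  binary_mask(array(TRUE, dim(template$voxels)), template$spacing,
              template$origin, template$axes)
}

expect_same_mask <- function(a, b) {
  expect_true(same_geometry(a, b))
  expect_identical(a$voxels, b$voxels)
}
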