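test_that("cube mesh reproduces closed-form volume and area", {
  d <- c(30, 30, 30)
  cube <- array(FALSE, d)
  cube[6:25, 6:25, 6:25] <- TRUE  # 20 voxels a side at 1 mm
  m <- mask_to_mesh(binary_mask(cube, 1))
  expect_lt(abs(mesh_volume(m) - 8000) / 8000, 0.05)
  expect_lt(abs(mesh_surface_area(m) - 2400) / 2400, 0.05)
  validate_mesh(m)
})

test_that("sphere-shell mesh volume matches the analytic shell", {
  rr <- radial_grid(c(81, 81, 81), c(1, 1, 1))
  shell <- binary_mask(rr > 30 & rr <= 35, 1, origin = c(-40, -40, -40))
  m <- mask_to_mesh(shell)
  va <- 4 / 3 * pi * (35^3 - 30^3)
  expect_lt(abs(mesh_volume(m) - va) / va, 0.02)
  # mesh volume agrees with the voxel volume of the mask
  expect_lt(abs(mesh_volume(m) - sum(shell$voxels)) / sum(shell$voxels), 0.03)
  validate_mesh(m)
})

test_that("meshing rejects empty and multi-component masks", {
  empty <- binary_mask(array(FALSE, c(5, 5, 5)), 1)
  expect_error(mask_to_mesh(empty), "empty mask")
  two <- array(FALSE, c(9, 9, 9))
  two[2:3, 2:3, 2:3] <- TRUE
  two[7:8, 7:8, 7:8] <- TRUE
  expect_error(mask_to_mesh(binary_mask(two, 1)), "2 connected components")
})

test_that("vertices are mapped to the patient frame", {
  block <- array(FALSE, c(5, 5, 5))
  block[2:4, 2:4, 2:4] <- TRUE
  org <- c(10, -20, 30)
  m <- mask_to_mesh(binary_mask(block, 2, org))
  # axis-aligned extremes are edge midpoints half a voxel beyond the
  # outermost voxel centers: origin + spacing*(1) - 1 .. origin + spacing*3 + 1
  for (ax in 1:3) {
    expect_equal(range(m$vertices[, ax]), org[ax] + c(1, 7), tolerance = 1e-12)
  }
  # same mask at unit spacing scales volume by spacing^3
  m1 <- mask_to_mesh(binary_mask(block, 1, c(0, 0, 0)))
  expect_equal(mesh_volume(m), 8 * mesh_volume(m1), tolerance = 1e-9)
})

test_that("watertightness validator catches open and degenerate meshes", {
  rr <- radial_grid(c(21, 21, 21), c(1, 1, 1))
  m <- mask_to_mesh(binary_mask(rr <= 7, 1, origin = rep(-10, 3)))
  expect_true(is_watertight(m))
  open <- triangle_mesh(m$vertices, m$faces[-1, ])
  expect_false(is_watertight(open))
  expect_error(validate_mesh(open), "2-manifold")
  degen <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(1, 2, 3)))
  expect_error(validate_mesh(degen), "degenerate")
})

test_that("Taubin smoothing preserves volume, topology, and the bound", {
  rr <- radial_grid(c(41, 41, 41), c(1, 1, 1))
  m <- mask_to_mesh(binary_mask(rr <= 15, 1, origin = rep(-20, 3)))
  expect_identical(smooth_mesh(m, iterations = 0), m)
  s <- smooth_mesh(m, iterations = 10, max_deviation_mm = 0.5)
  expect_true(is_watertight(s))
  expect_lt(abs(mesh_volume(s) - mesh_volume(m)) / mesh_volume(m), 0.02)
  disp <- sqrt(rowSums((s$vertices - m$vertices)^2))
  expect_lte(max(disp), 0.5 + 1e-12)
  tight <- smooth_mesh(m, iterations = 10, max_deviation_mm = 0.1)
  expect_lte(max(sqrt(rowSums((tight$vertices - m$vertices)^2))), 0.1 + 1e-12)
})

test_that("binary STL round-trips at 32-bit float precision", {
  patch <- triangle_mesh(
    rbind(c(0, 0, 0), c(10.25, 0, 0), c(10.25, 7.5, 0), c(0, 7.5, 0),
          c(5, 3, 8.125)),
    rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5), c(1, 4, 3),
          c(1, 3, 2))
  )
  f <- tempfile(fileext = ".stl")
  write_stl(patch, f)
  back <- read_stl(f)
  # all fixture coordinates are exactly representable in float32
  expect_equal(sort(back$vertices[, 1]), sort(patch$vertices[, 1]))
  expect_equal(mesh_volume(back), mesh_volume(patch), tolerance = 1e-6)
  expect_true(is_watertight(back))
})

test_that("STL file size is exactly 84 + 50 * facets and truncation errors", {
  rr <- radial_grid(c(31, 31, 31), c(1, 1, 1))
  m <- mask_to_mesh(binary_mask(rr <= 10, 1, origin = rep(-15, 3)))
  f <- tempfile(fileext = ".stl")
  write_stl(m, f)
  expect_equal(file.size(f), 84 + 50 * nrow(m$faces))
  r2 <- read_stl(f)
  expect_equal(nrow(r2$faces), nrow(m$faces))
  expect_equal(mesh_volume(r2), mesh_volume(m), tolerance = 1e-5)
  # truncated mid-facet
  raw_all <- readBin(f, "raw", file.size(f))
  f2 <- tempfile(fileext = ".stl")
  writeBin(raw_all[1:(length(raw_all) - 17)], f2)
  expect_error(read_stl(f2), "does not match")
  f3 <- tempfile(fileext = ".stl")
  writeBin(raw_all[1:50], f3)
  expect_error(read_stl(f3), "shorter than 84")
})

test_that("deterministic export: same mesh gives byte-identical files", {
  rr <- radial_grid(c(21, 21, 21), c(1, 1, 1))
  m <- mask_to_mesh(binary_mask(rr <= 6, 1, origin = rep(-10, 3)))
  f1 <- tempfile(fileext = ".stl")
  f2 <- tempfile(fileext = ".stl")
  write_stl(m, f1)
  write_stl(m, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("voxelization inverts meshing up to the surface layer", {
  rr <- radial_grid(c(41, 41, 41), c(1, 1, 1))
  mask <- binary_mask(rr <= 14, 1, origin = rep(-20, 3))
  m <- mask_to_mesh(mask)
  back <- voxelize_mesh(m, mask)
  mismatch <- sum(back$voxels != mask$voxels)
  expect_lt(mismatch / sum(mask$voxels), 0.005)
  # all mismatches, if any, sit on the surface
  surf <- boluscap:::.surface_voxels(mask$voxels) |
    boluscap:::.surface_voxels(back$voxels)
  expect_true(all(which(back$voxels != mask$voxels) %in% which(surf)))
})
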