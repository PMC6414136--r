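test_that("volume and mask constructors enforce their invariants", {
  a <- array(0, c(4, 4, 4))
  expect_error(ct_volume(a, spacing = c(1, 0, 1)), "positive")
  expect_error(ct_volume(a, 1, axes = matrix(c(1, 0, 0, 1, 0, 0, 0, 0, 1), 3)),
               "orthonormal")
  expect_error(ct_volume(array(5000, c(2, 2, 2)), 1), "3071")
  expect_error(ct_volume(array(-2000, c(2, 2, 2)), 1), "-1024")
  v <- ct_volume(a, 1)
  expect_s3_class(v, "ct_volume")
  expect_equal(v$spacing, c(1, 1, 1))
  expect_error(binary_mask(array(1, c(2, 2, 2)), 1), "logical")
})

test_that("NIfTI container round-trips voxels and LPS geometry exactly", {
  set.seed(42)
  vox <- array(round(rnorm(4 * 5 * 6, 0, 200)), c(4, 5, 6))
  vox <- pmin(pmax(vox, -1024), 3071)
  # a non-trivial but orthonormal orientation: 90-degree axis permutation
  axes <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  v <- ct_volume(vox, spacing = c(0.7, 0.7, 2.5), origin = c(-10, 20, -30),
                 axes = axes)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$voxels, v$voxels)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-5)
  expect_equal(v2$axes, v$axes, tolerance = 1e-6)

  m <- binary_mask(vox > 0, c(0.7, 0.7, 2.5), c(-10, 20, -30), axes)
  fm <- tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  m2 <- read_volume(fm, mask = TRUE)
  expect_same_mask(m, m2)
})

test_that("a written DICOM series reads back with identical HU and geometry", {
  set.seed(7)
  stored <- array(sample.int(3000, 6 * 5 * 10, replace = TRUE), c(6, 5, 10))
  dir <- withr::local_tempdir()
  write_test_dicom_series(dir, stored, pixel_spacing = c(0.8, 0.6),
                          z0 = -12, dz = 3, origin_xy = c(-20, -15),
                          slope = 1, intercept = -1024)
  ct <- read_ct_series(dir)
  expect_equal(dim(ct$voxels), c(6, 5, 10))
  # PixelSpacing is (row, column) spacing = (y, x)
  expect_equal(ct$spacing, c(0.6, 0.8, 3))
  expect_equal(ct$origin, c(-20, -15, -12))
  expect_equal(ct$axes, diag(3))
  expect_equal(ct$voxels, stored - 1024)
})

test_that("rescale slope/intercept map stored values to HU", {
  stored <- array(1024L, c(4, 4, 3))
  stored[1, 1, 1] <- 0L
  dir <- withr::local_tempdir()
  write_test_dicom_series(dir, stored, slope = 1, intercept = -1024)
  ct <- read_ct_series(dir)
  expect_equal(ct$voxels[2, 2, 2], 0)      # 1*1024 - 1024
  expect_equal(ct$voxels[1, 1, 1], -1024)  # 1*0 - 1024
  dir2 <- withr::local_tempdir()
  write_test_dicom_series(dir2, stored, slope = 2, intercept = -1000)
  expect_equal(read_ct_series(dir2)$voxels[2, 2, 2], 1048)
})

test_that("incoherent series are rejected with informative errors", {
  stored <- array(1000L, c(4, 4, 6))
  dir <- withr::local_tempdir()
  write_test_dicom_series(dir, stored, drop_slice = 3)
  expect_error(read_ct_series(dir), "non-uniform slice spacing")

  dir2 <- withr::local_tempdir()
  write_test_dicom_series(dir2, stored)
  write_test_dicom_slice(file.path(dir2, "intruder.dcm"), stored[, , 1],
                         ipp = c(0, 0, 99), instance = 99,
                         series_uid = "9.9.9")
  expect_error(read_ct_series(dir2), "mixed series")

  dir3 <- withr::local_tempdir()
  write_test_dicom_series(dir3, stored)
  write_test_dicom_slice(file.path(dir3, "dupe.dcm"), stored[, , 2],
                         ipp = c(0, 0, 1), instance = 50)
  expect_error(read_ct_series(dir3), "duplicate slice position")

  expect_error(read_ct_series(withr::local_tempdir()), "no files")
})

test_that("the reader agrees with pydicom-written files", {
  expect_true(nzchar(Sys.which("python")))
  dir <- withr::local_tempdir()
  script <- file.path(dir, "make_series.py")
  writeLines(c(
    "import numpy as np",
    "import pydicom",
    "from pydicom.dataset import Dataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, generate_uid",
    "import sys, os",
    "outdir = sys.argv[1]",
    "suid = generate_uid()",
    "rng = np.random.default_rng(11)",
    "vol = rng.integers(0, 3000, size=(4, 6, 5), dtype=np.uint16)  # z,rows,cols",
    "for k in range(4):",
    "    ds = Dataset()",
    "    ds.SOPClassUID = '1.2.840.10008.5.1.4.1.1.2'",
    "    ds.SOPInstanceUID = generate_uid()",
    "    ds.Modality = 'CT'",
    "    ds.SeriesInstanceUID = suid",
    "    ds.InstanceNumber = k + 1",
    "    ds.ImagePositionPatient = [-12.0, -8.0, 2.5 * k]",
    "    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]",
    "    ds.PixelSpacing = [0.5, 0.9]",
    "    ds.Rows, ds.Columns = 6, 5",
    "    ds.SamplesPerPixel = 1",
    "    ds.PhotometricInterpretation = 'MONOCHROME2'",
    "    ds.BitsAllocated = ds.BitsStored = 16",
    "    ds.HighBit = 15",
    "    ds.PixelRepresentation = 0",
    "    ds.RescaleSlope = 1",
    "    ds.RescaleIntercept = -1024",
    "    ds.PixelData = vol[k].tobytes()",
    "    meta = FileMetaDataset()",
    "    meta.TransferSyntaxUID = ExplicitVRLittleEndian",
    "    meta.MediaStorageSOPClassUID = ds.SOPClassUID",
    "    meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID",
    "    ds.file_meta = meta",
    "    ds.save_as(os.path.join(outdir, f'ct_{k}.dcm'), enforce_file_format=True)",
    "np.save(os.path.join(outdir, 'vol.npy'), vol)",
    "print('OK')"
  ), script)
  res <- suppressWarnings(
    system2("python", c(script, dir), stdout = TRUE, stderr = TRUE)
  )
  expect_true(any(grepl("^OK$", res)))
  file.remove(script)
  file.remove(file.path(dir, "vol.npy"))
  ct <- read_ct_series(dir)
  expect_equal(dim(ct$voxels), c(5, 6, 4))
  expect_equal(ct$spacing, c(0.9, 0.5, 2.5))
  expect_equal(ct$origin, c(-12, -8, 0))
  # independent HU check at a handful of voxels via python
  rng_check <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import numpy as np; rng=np.random.default_rng(11); ",
    "v=rng.integers(0,3000,size=(4,6,5),dtype=np.uint16); ",
    "print(v[0,0,0], v[2,3,1], v[3,5,4])"
  ))), stdout = TRUE))
  vals <- as.numeric(strsplit(rng_check[length(rng_check)], " ")[[1]])
  # vol[k, row, col] -> voxels[col+1, row+1, k+1]
  expect_equal(ct$voxels[1, 1, 1], vals[1] - 1024)
  expect_equal(ct$voxels[2, 4, 3], vals[2] - 1024)
  expect_equal(ct$voxels[5, 6, 4], vals[3] - 1024)
})

test_that("resampling preserves constants, identity, and physical extent", {
  v <- ct_volume(array(40, c(9, 9, 5)), spacing = c(1, 1, 3))
  expect_identical(resample_isotropic(v, 1)$voxels[1], 40)
  expect_true(all(resample_isotropic(v, 1)$voxels == 40))
  same <- ct_volume(array(40, c(9, 9, 5)), spacing = 1)
  expect_identical(resample_isotropic(same, 1), same)
  out <- resample_isotropic(v, 1)
  expect_equal(dim(out$voxels), c(9, 9, 13))
  expect_error(resample_isotropic(v, -1), "positive")
  expect_error(resample_isotropic(v, 0), "positive")
})

test_that("mask resampling recovers analytic volume and keeps the center", {
  r <- 40
  spacing <- c(1, 1, 3)
  dims <- c(101, 101, 35)
  rr <- radial_grid(dims, spacing)
  m <- binary_mask(rr <= r, spacing, origin = -(dims - 1) / 2 * spacing)
  out <- resample_isotropic(m, 1)
  vol <- sum(out$voxels) * 1
  expect_lt(abs(vol - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.02)
  # bounding box center moves by less than one target voxel
  center_mm <- function(mask) {
    idx <- which(mask$voxels, arr.ind = TRUE)
    colMeans(sweep(idx - 1, 2, mask$spacing, "*")) + mask$origin
  }
  expect_lt(max(abs(center_mm(out) - center_mm(m))), 1)
})
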