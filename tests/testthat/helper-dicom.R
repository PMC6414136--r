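# Minimal DICOM writer for test fixtures (explicit VR little endian,
# part-10). Written independently of the package's reader so round-trip
# tests exercise a genuine encode/decode pair.

.le16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.le32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) value <- charToRaw(value)
  if (length(value) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value <- c(value, pad)
  }
  tag <- c(.le16(group), .le16(elem))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)), .le32(length(value)), value)
  } else {
    c(tag, charToRaw(vr), .le16(length(value)), value)
  }
}

# Write one CT slice; `stored` is a cols x rows integer matrix of stored
# pixel values (column index fastest, matching the package's array layout).
write_test_dicom_slice <- function(path, stored, ipp, instance,
                                   series_uid = "1.2.3.4.5",
                                   pixel_spacing = c(1, 1),
                                   iop = c(1, 0, 0, 0, 1, 0),
                                   slope = 1, intercept = -1024,
                                   signed = FALSE) {
  cols <- nrow(stored)
  rows <- ncol(stored)
  # pixel order on disk is row-major: row 1 (all columns) first
  px <- writeBin(as.integer(as.vector(stored)), raw(), size = 2L,
                 endian = "little")
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                          collapse = "\\")
  body <- c(
    .dcm_elem(0x0008, 0x0060, "CS", "CT"),
    .dcm_elem(0x0020, 0x000E, "UI", series_uid),
    .dcm_elem(0x0020, 0x0013, "IS", as.character(instance)),
    .dcm_elem(0x0020, 0x0032, "DS", ds(ipp)),
    .dcm_elem(0x0020, 0x0037, "DS", ds(iop)),
    .dcm_elem(0x0028, 0x0002, "US", .le16(1L)),
    .dcm_elem(0x0028, 0x0010, "US", .le16(rows)),
    .dcm_elem(0x0028, 0x0011, "US", .le16(cols)),
    .dcm_elem(0x0028, 0x0030, "DS", ds(pixel_spacing)),
    .dcm_elem(0x0028, 0x0100, "US", .le16(16L)),
    .dcm_elem(0x0028, 0x0101, "US", .le16(16L)),
    .dcm_elem(0x0028, 0x0103, "US", .le16(if (signed) 1L else 0L)),
    .dcm_elem(0x0028, 0x1052, "DS", format(intercept)),
    .dcm_elem(0x0028, 0x1053, "DS", format(slope)),
    .dcm_elem(0x7FE0, 0x0010, "OW", px)
  )
  meta <- .dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# Write a full axial series into `dir`; `stored` is a 3D array
# (cols x rows x slices). Slice k sits at z = z0 + (k-1)*dz. File names are
# deliberately shuffled so readers must sort by position, not name.
write_test_dicom_series <- function(dir, stored, pixel_spacing = c(1, 1),
                                    z0 = 0, dz = 1, origin_xy = c(0, 0),
                                    series_uid = "1.2.3.4.5",
                                    slope = 1, intercept = -1024,
                                    shuffle_names = TRUE, drop_slice = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(stored)[3]
  keep <- setdiff(seq_len(n), drop_slice)
  names_pool <- sprintf("slice_%03d.dcm", seq_along(keep))
  if (shuffle_names) names_pool <- rev(names_pool)
  for (q in seq_along(keep)) {
    k <- keep[q]
    write_test_dicom_slice(
      file.path(dir, names_pool[q]), stored[, , k],
      ipp = c(origin_xy, z0 + (k - 1) * dz), instance = k,
      series_uid = series_uid, pixel_spacing = pixel_spacing,
      slope = slope, intercept = intercept
    )
  }
  invisible(dir)
}
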