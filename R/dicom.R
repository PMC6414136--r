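# Minimal DICOM (PS3.10) reader for axial CT series: little-endian implicit
# and explicit VR transfer syntaxes, uncompressed 16-bit pixel data. Only the
# tags needed to reconstruct the HU grid and its geometry are interpreted;
# everything else is skipped structurally.

.u16 <- function(r, pos) {
  as.integer(r[pos]) + 256L * as.integer(r[pos + 1L])
}

.u32 <- function(r, pos) {
  # double arithmetic: lengths can exceed .Machine$integer.max sentinel-wise
  as.numeric(r[pos]) + 256 * as.numeric(r[pos + 1L]) +
    65536 * as.numeric(r[pos + 2L]) + 16777216 * as.numeric(r[pos + 3L])
}

.dicom_string <- function(val) {
  trimws(rawToChar(val[val != as.raw(0)]))
}

.dicom_numbers <- function(val) {
  as.numeric(strsplit(.dicom_string(val), "\\\\")[[1]])
}

.LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# VRs for the tags we interpret, used under implicit VR little endian.
.TAG_VR <- c(
  "00080060" = "CS", "0020000E" = "UI", "00200013" = "IS",
  "00200032" = "DS", "00200037" = "DS",
  "00280002" = "US", "00280010" = "US", "00280011" = "US",
  "00280030" = "DS", "00280100" = "US", "00280101" = "US",
  "00280103" = "US", "00281052" = "DS", "00281053" = "DS",
  "7FE00010" = "OW"
)

.SEQ_DELIM <- as.raw(c(0xfe, 0xff, 0xdd, 0xe0))

# Parse one element starting at pos; returns list(tag, vr, value raw, next_pos)
.parse_element <- function(r, pos, explicit) {
  grp <- .u16(r, pos)
  el <- .u16(r, pos + 2L)
  tag <- sprintf("%04X%04X", grp, el)
  if (explicit) {
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .u32(r, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- .u16(r, pos + 6L)
      vstart <- pos + 8L
    }
  } else {
    vr <- if (tag %in% names(.TAG_VR)) .TAG_VR[[tag]] else "UN"
    len <- .u32(r, pos + 4L)
    vstart <- pos + 8L
  }
  if (len == 4294967295) {
    # undefined length (sequence/encapsulation): scan for the sequence
    # delimitation item and skip the whole construct uninterpreted
    hit <- vstart
    repeat {
      if (hit + 7L > length(r)) stop("unterminated undefined-length element")
      if (identical(r[hit:(hit + 3L)], .SEQ_DELIM)) break
      hit <- hit + 1L
    }
    return(list(tag = tag, vr = vr, value = NULL, next_pos = hit + 8L))
  }
  len <- as.integer(len)
  value <- if (len > 0L) r[vstart:(vstart + len - 1L)] else raw(0)
  list(tag = tag, vr = vr, value = value, next_pos = vstart + len)
}

# Parse a single CT slice file into the fields needed for volume assembly.
.parse_dicom_slice <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 132L || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  pos <- 133L
  transfer_syntax <- "1.2.840.10008.1.2.1"
  # file meta information group (0002): always explicit VR little endian
  while (pos + 7L <= length(r) && .u16(r, pos) == 2L) {
    e <- .parse_element(r, pos, explicit = TRUE)
    if (e$tag == "00020010") transfer_syntax <- .dicom_string(e$value)
    pos <- e$next_pos
  }
  explicit <- transfer_syntax != "1.2.840.10008.1.2"
  if (!transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
    stop("unsupported transfer syntax ", transfer_syntax, " in ", path)
  }
  out <- list(path = path, rescale_slope = 1, rescale_intercept = 0,
              pixel_representation = 0L, bits_allocated = 16L)
  while (pos + 7L <= length(r)) {
    e <- .parse_element(r, pos, explicit = explicit)
    pos <- e$next_pos
    if (is.null(e$value)) next
    switch(e$tag,
      "00080060" = { out$modality <- .dicom_string(e$value) },
      "0020000E" = { out$series_uid <- .dicom_string(e$value) },
      "00200032" = { out$ipp <- .dicom_numbers(e$value) },
      "00200037" = { out$iop <- .dicom_numbers(e$value) },
      "00280010" = { out$rows <- .u16(e$value, 1L) },
      "00280011" = { out$cols <- .u16(e$value, 1L) },
      "00280030" = { out$pixel_spacing <- .dicom_numbers(e$value) },
      "00280100" = { out$bits_allocated <- .u16(e$value, 1L) },
      "00280103" = { out$pixel_representation <- .u16(e$value, 1L) },
      "00281052" = { out$rescale_intercept <- .dicom_numbers(e$value)[1] },
      "00281053" = { out$rescale_slope <- .dicom_numbers(e$value)[1] },
      "7FE00010" = { out$pixel_data <- e$value },
      NULL)
  }
  out
}

#' Read an axial CT series from a directory of DICOM files
#'
#' Reads every DICOM file in `directory_path`, verifies that the files form a
#' single coherent axial series, sorts slices by their position along the
#' slice normal, applies the per-series rescale slope/intercept to obtain HU,
#' and assembles a [ct_volume()]. HU values are clipped to the 12-bit CT
#' range `[-1024, 3071]`.
#'
#' Little-endian implicit and explicit VR uncompressed transfer syntaxes are
#' supported (the formats CT scanners export for axial series). DICOM is a
#' read-only format here; use [write_volume()] for the package's own
#' container.
#'
#' @param directory_path Directory containing one CT series, one slice per
#'   file.
#' @return A [ct_volume()] with geometry taken from the series headers.
#' @export
read_ct_series <- function(directory_path) {
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files found in ", directory_path)
  slices <- lapply(files, .parse_dicom_slice)
  slices <- Filter(function(s) !is.null(s$pixel_data), slices)
  if (length(slices) < 2L) {
    stop("need at least two image slices to assemble a series")
  }
  uids <- vapply(slices, function(s) s$series_uid %||% "", "")
  if (length(unique(uids)) != 1L) {
    stop("mixed series identifiers in directory: ",
         paste(unique(uids), collapse = ", "))
  }
  for (fld in c("rows", "cols", "pixel_spacing", "iop", "ipp")) {
    if (any(vapply(slices, function(s) is.null(s[[fld]]), TRUE))) {
      stop("slice missing required header field: ", fld)
    }
  }
  iop0 <- slices[[1]]$iop
  iop_dev <- max(vapply(slices, function(s) max(abs(s$iop - iop0)), 0))
  if (iop_dev > 1e-5) stop("inconsistent image orientation across slices")
  rows0 <- slices[[1]]$rows
  cols0 <- slices[[1]]$cols
  if (any(vapply(slices, function(s) s$rows != rows0 || s$cols != cols0, TRUE))) {
    stop("inconsistent image matrix size across slices")
  }

  row_dir <- iop0[1:3]  # direction of increasing column index
  col_dir <- iop0[4:6]  # direction of increasing row index
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  proj <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]
  proj <- proj[ord]
  gaps <- diff(proj)
  if (any(gaps < 1e-4)) {
    stop(sprintf("duplicate slice positions at %.3f mm along the slice normal",
                 proj[which(gaps < 1e-4)[1]]))
  }
  dz <- median(gaps)
  bad <- which(abs(gaps - dz) > pmax(1e-3, 1e-3 * dz))
  if (length(bad) > 0L) {
    stop(sprintf(paste0("non-uniform slice spacing: gap of %.3f mm between ",
                        "slice positions %.3f and %.3f (expected %.3f mm)"),
                 gaps[bad[1]], proj[bad[1]], proj[bad[1] + 1L], dz))
  }

  nslice <- length(slices)
  vox <- array(0, dim = c(cols0, rows0, nslice))
  for (s in seq_len(nslice)) {
    sl <- slices[[s]]
    if (sl$bits_allocated != 16L) {
      stop("only 16-bit pixel data is supported (got ", sl$bits_allocated,
           " bits in ", sl$path, ")")
    }
    n_px <- rows0 * cols0
    if (length(sl$pixel_data) < 2L * n_px) {
      stop("pixel data shorter than Rows x Columns in ", sl$path)
    }
    stored <- readBin(sl$pixel_data, integer(), n = n_px, size = 2L,
                      signed = sl$pixel_representation == 1L,
                      endian = "little")
    hu <- sl$rescale_slope * stored + sl$rescale_intercept
    vox[, , s] <- matrix(hu, nrow = cols0)  # pixel order is row-major
  }
  vox <- pmin(pmax(vox, -1024), 3071)
  ps <- slices[[1]]$pixel_spacing  # (row spacing, column spacing)
  ct_volume(vox,
            spacing = c(ps[2], ps[1], dz),
            origin = slices[[1]]$ipp,
            axes = cbind(row_dir, col_dir, normal, deparse.level = 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
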