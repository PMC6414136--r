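#' Absolute percent difference between planned and measured dose
#'
#' `100 * |measured - planned| / planned`: the planned (TPS-calculated) dose
#' is the denominator, matching the direction in which planned-vs-measured
#' agreement is reported clinically.
#'
#' @param planned Planned dose, cGy (> 0).
#' @param measured Measured dose, cGy.
#' @return Percent difference (vectorized).
#' @export
abs_percent_difference <- function(planned, measured) {
  if (any(planned <= 0)) stop("planned dose must be positive")
  100 * abs(measured - planned) / planned
}

#' Read TLD records from delimited text
#'
#' Accepts either raw doses or precomputed differences. Columns are matched
#' by name (case-insensitive): `location` (or `id`), then either `planned`
#' and `measured` doses in cGy, or a single `abs_pct` (aliases
#' `percent_diff`, `abs_percent_diff`) column. An optional `fraction` column
#' marks multi-fraction in vivo measurements.
#'
#' @param path Whitespace-, tab- or comma-separated file with a header line.
#' @return A data.frame of class `tld_records`.
#' @export
read_tld_records <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- read.table(path, sep = sep, header = TRUE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  loc <- intersect(c("location", "location_id", "id"), names(df))[1]
  if (is.na(loc)) stop("no location column found in ", path)
  out <- data.frame(location = df[[loc]])
  pct <- intersect(c("abs_pct", "percent_diff", "abs_percent_diff"),
                   names(df))[1]
  if (all(c("planned", "measured") %in% names(df))) {
    out$planned <- as.numeric(df$planned)
    out$measured <- as.numeric(df$measured)
    if (any(out$planned <= 0) || any(out$measured <= 0)) {
      stop("doses must be positive")
    }
  } else if (!is.na(pct)) {
    out$abs_pct <- as.numeric(gsub("%", "", as.character(df[[pct]])))
  } else {
    stop("need either planned+measured columns or an abs_pct column in ",
         path)
  }
  if ("fraction" %in% names(df)) out$fraction <- df$fraction
  class(out) <- c("tld_records", "data.frame")
  out
}

.tld_abs_pct <- function(records) {
  if (!is.null(records$abs_pct)) {
    as.numeric(records$abs_pct)
  } else if (!is.null(records$planned) && !is.null(records$measured)) {
    abs_percent_difference(records$planned, records$measured)
  } else {
    stop("records carry neither doses nor precomputed percent differences")
  }
}

#' Summarize planned-vs-measured dose agreement
#'
#' Computes the absolute percent differences (from doses, or uses the
#' precomputed column) and summarizes them: mean, sample (n-1) standard
#' deviation, maximum, and the fraction of locations within a tolerance.
#'
#' @param records A `tld_records` data.frame (see [read_tld_records()]), or
#'   any data.frame with `planned`/`measured` or `abs_pct` columns.
#' @param tolerance_pct Agreement tolerance for `fraction_within`
#'   (default 5).
#' @return An object of class `dose_comparison_summary`: list with `n`,
#'   `mean_abs_pct`, `sd_abs_pct`, `max_abs_pct`, `fraction_within`,
#'   `tolerance_pct` and `sd_defined` (`FALSE` when n = 1, in which case the
#'   SD is reported as 0).
#' @export
summarize_dose_comparison <- function(records, tolerance_pct = 5) {
  pct <- .tld_abs_pct(records)
  if (length(pct) < 1L) stop("no TLD records to summarize")
  n <- length(pct)
  structure(
    list(n = n,
         mean_abs_pct = mean(pct),
         sd_abs_pct = if (n > 1L) sd(pct) else 0,
         sd_defined = n > 1L,
         max_abs_pct = max(pct),
         fraction_within = mean(pct <= tolerance_pct),
         tolerance_pct = tolerance_pct),
    class = "dose_comparison_summary"
  )
}

#' @export
print.dose_comparison_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<dose_comparison_summary> n = %d\n",
           "  mean |%%diff| %.1f%%  sd %.1f%%%s  max %.1f%%\n",
           "  within %.3g%%: %.0f%%\n"),
    x$n, x$mean_abs_pct, x$sd_abs_pct,
    if (x$sd_defined) "" else " (n = 1; SD undefined, reported as 0)",
    x$max_abs_pct, x$tolerance_pct, 100 * x$fraction_within))
  invisible(x)
}

#' Summarize multi-fraction in vivo TLD measurements
#'
#' For records measured over several treatment fractions: each fraction is
#' summarized on its own ([summarize_dose_comparison()]), the per-fraction
#' mean errors are averaged, and the interfraction standard deviation is the
#' per-location SD of the percent difference across fractions, averaged over
#' locations.
#'
#' @param records A `tld_records` data.frame with a `fraction` column.
#' @param tolerance_pct Passed to the per-fraction summaries.
#' @return List with `per_fraction` (named list of summaries),
#'   `mean_abs_pct` (average of per-fraction means), `max_abs_pct`, and
#'   `interfraction_sd` (mean over locations of the across-fraction SD).
#' @export
summarize_fractions <- function(records, tolerance_pct = 5) {
  if (is.null(records$fraction)) stop("records have no fraction column")
  pct <- .tld_abs_pct(records)
  frs <- split(seq_along(pct), records$fraction)
  per_fraction <- lapply(frs, function(ix) {
    summarize_dose_comparison(records[ix, , drop = FALSE], tolerance_pct)
  })
  by_loc <- split(pct, records$location)
  sds <- vapply(by_loc, function(v) if (length(v) > 1L) sd(v) else NA_real_, 0)
  list(per_fraction = per_fraction,
       mean_abs_pct = mean(vapply(per_fraction, `[[`, 0, "mean_abs_pct")),
       max_abs_pct = max(pct),
       interfraction_sd = mean(sds, na.rm = TRUE))
}

#' Packaged TLD fixture: phantom-study percent differences
#'
#' Returns the path of the packaged 20-location phantom-study TLD table
#' (absolute percent difference between planned and measured dose per scalp
#' location), shipped as tab-separated text.
#'
#' @return File path of the fixture.
#' @export
tld_phantom_table <- function() {
  system.file("extdata", "tld_phantom_study.tsv", package = "boluscap",
              mustWork = TRUE)
}

#' Packaged generic CT calibration curve
#'
#' A representative generic HU-to-density table (synthetic, typical of
#' clinical CT calibration curves; scanner-specific curves should be supplied
#' by the user as delimited text).
#'
#' @return File path of the fixture.
#' @export
generic_calibration_curve <- function() {
  system.file("extdata", "calibration_curve_generic.tsv",
              package = "boluscap", mustWork = TRUE)
}
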