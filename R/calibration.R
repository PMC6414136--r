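#' CT calibration curve (HU to physical density)
#'
#' Ordered knots of the scanner-specific piecewise-linear map from CT number
#' to physical density, as used by treatment planning systems for
#' heterogeneity correction.
#'
#' @param hu Numeric vector of knot HU values, strictly increasing.
#' @param density Numeric vector of knot densities in g/cm^3, all > 0.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(hu, density) {
  hu <- as.numeric(hu)
  density <- as.numeric(density)
  if (length(hu) < 2L) stop("a calibration curve needs at least 2 knots")
  stopifnot(length(hu) == length(density))
  if (any(diff(hu) <= 0)) stop("knot HU values must be strictly increasing")
  if (any(density <= 0)) stop("knot densities must be positive")
  structure(list(hu = hu, density = density), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d knots, HU [%g, %g] -> density [%g, %g] g/cm^3\n",
              length(x$hu), min(x$hu), max(x$hu), min(x$density),
              max(x$density)))
  invisible(x)
}

#' Read a calibration curve from delimited text
#'
#' Two columns per line (HU, density in g/cm^3), whitespace- or
#' comma-separated, optional header line.
#'
#' @param path File path.
#' @return A [calibration_curve()].
#' @export
read_calibration_curve <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("[A-Za-df-z]", first)  # letters other than e/E (exponents)
  df <- read.table(path, sep = sep, header = header,
                   strip.white = TRUE)
  if (ncol(df) < 2L) stop("expected two columns (hu, density) in ", path)
  calibration_curve(df[[1]], df[[2]])
}

#' Predict density from CT number via a calibration curve
#'
#' Piecewise-linear interpolation between knots, linear extrapolation beyond
#' the end knots, floored at 0 g/cm^3.
#'
#' @param curve A [calibration_curve()].
#' @param hu Numeric vector of CT numbers.
#' @return Densities in g/cm^3, same length as `hu`.
#' @export
predict_density <- function(curve, hu) {
  stopifnot(inherits(curve, "calibration_curve"))
  h <- curve$hu
  d <- curve$density
  i <- findInterval(hu, h, all.inside = TRUE)
  out <- d[i] + (hu - h[i]) * (d[i + 1L] - d[i]) / (h[i + 1L] - h[i])
  pmax(out, 0)
}

#' Percent error of a predicted density against the measured density
#'
#' `100 * |predicted - measured| / measured`; the physically measured
#' (mass/dimensions) density is the reference.
#'
#' @param predicted Predicted density, g/cm^3.
#' @param measured Measured density, g/cm^3 (> 0).
#' @return Percent error (vectorized).
#' @export
density_percent_error <- function(predicted, measured) {
  if (any(measured <= 0)) stop("measured density must be positive")
  100 * abs(predicted - measured) / measured
}
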