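#' Air-gap map: conformality of a bolus to the skin surface
#'
#' For every body-surface voxel inside the cap extent, the air gap is the
#' Euclidean distance from the voxel center to the nearest bolus voxel
#' center, minus half a voxel diagonal (the sampling offset between two
#' adjacent voxel centers), floored at 0. A shell built by
#' [build_bolus_shell()] directly on its body therefore reports gap 0 within
#' voxel tolerance; a physically displaced bolus reports the displacement.
#' Gaps are genuine 3D distances, independent of slice orientation, and are
#' evaluated only inside the extent because the cap rim necessarily diverges
#' from the scalp.
#'
#' @param body Body [binary_mask()].
#' @param bolus Bolus [binary_mask()] on the same grid.
#' @param extent Cap extent [binary_mask()] on the same grid.
#' @return An object of class `gap_map`: list with `distances_mm`
#'   (per-sample gaps) and `summary` (`max`, `mean`, `p95`, all mm, plus `n`).
#' @export
air_gap_map <- function(body, bolus, extent) {
  stopifnot(inherits(body, "binary_mask"), inherits(bolus, "binary_mask"),
            inherits(extent, "binary_mask"))
  .stop_if_geometry_differs(body, bolus)
  .stop_if_geometry_differs(body, extent)
  if (!any(bolus$voxels & extent$voxels)) {
    stop("bolus is empty inside the cap extent")
  }
  surf <- .surface_voxels(body$voxels) & extent$voxels
  if (!any(surf)) stop("no body-surface voxels inside the cap extent")
  d_bolus <- .edt_arr(bolus$voxels, bolus$spacing)
  half_diag <- 0.5 * sqrt(sum(body$spacing^2))
  gaps <- pmax(0, d_bolus[surf] - half_diag)
  structure(
    list(distances_mm = gaps,
         summary = list(n = length(gaps), max = max(gaps), mean = mean(gaps),
                        p95 = unname(quantile(gaps, 0.95)))),
    class = "gap_map"
  )
}

#' @export
print.gap_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<gap_map> %d surface samples: max %.2f mm, mean %.2f mm, p95 %.2f mm\n",
    s$n, s$max, s$mean, s$p95))
  invisible(x)
}

#' Wall-thickness map of a bolus shell
#'
#' Thickness is sampled at the shell's inner surface (bolus voxels adjacent
#' to the body) inside the cap extent, as the Euclidean distance to the
#' nearest outside-air voxel (neither bolus nor body) -- a double distance
#' transform through the wall along the outward surface normal.
#'
#' @inheritParams air_gap_map
#' @return An object of class `thickness_map`: list with `thickness_mm`
#'   (per-sample values) and `summary` (`median`, `min`, `max`, mm, plus `n`).
#' @export
thickness_map <- function(bolus, body, extent) {
  stopifnot(inherits(body, "binary_mask"), inherits(bolus, "binary_mask"),
            inherits(extent, "binary_mask"))
  .stop_if_geometry_differs(body, bolus)
  .stop_if_geometry_differs(body, extent)
  if (!any(bolus$voxels)) stop("bolus mask is empty")
  outside <- !(bolus$voxels | body$voxels)
  d_out <- .edt_arr(outside, bolus$spacing)
  inner <- bolus$voxels & .dilate6(body$voxels) & extent$voxels
  if (!any(inner)) stop("no inner-surface bolus voxels inside the cap extent")
  th <- d_out[inner]
  structure(
    list(thickness_mm = th,
         summary = list(n = length(th), median = median(th), min = min(th),
                        max = max(th))),
    class = "thickness_map"
  )
}

#' @export
print.thickness_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<thickness_map> %d samples: median %.2f mm, range [%.2f, %.2f] mm\n",
    s$n, s$median, s$min, s$max))
  invisible(x)
}

#' Write a combined QA report (gap + thickness) as delimited text
#'
#' @param gap A `gap_map` from [air_gap_map()].
#' @param thickness A `thickness_map` from [thickness_map()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(gap, thickness, path) {
  df <- data.frame(
    metric = c("air_gap_max_mm", "air_gap_mean_mm", "air_gap_p95_mm",
               "air_gap_n_samples", "thickness_median_mm", "thickness_min_mm",
               "thickness_max_mm", "thickness_n_samples"),
    value = c(gap$summary$max, gap$summary$mean, gap$summary$p95,
              gap$summary$n, thickness$summary$median, thickness$summary$min,
              thickness$summary$max, thickness$summary$n)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
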