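# Relative tracer leakage index: tracer signal density in a fixed band on
# the abluminal (brain-facing) side of the claudin-5 ring, normalized so the
# reference group's mean density defines index 1.

#' Build the abluminal measurement band
#'
#' The band is the region between the outward offsets of the claudin-5 ring
#' polygon at `inner_offset_nm` and `outer_offset_nm` (defaults 100 and
#' 300 nm). "Abluminal" is operationalized as the outward normal side of the
#' ring - away from the lumen. The ring polygon must be convex (annotate the
#' convex hull of the claudin-5 signal if the raw outline is not; see
#' [ring_from_localizations()]): for a convex ring the offset region is a
#' Minkowski sum with a disc and its area has the exact closed form
#' `P*(outer - inner) + pi*(outer^2 - inner^2)` with `P` the ring perimeter.
#' Membership tests use exact point-to-boundary distances, not the
#' discretized QC polygons.
#'
#' @param ring A convex [capillary_roi()] tracing the claudin-5 ring.
#' @param inner_offset_nm,outer_offset_nm Band offsets in nm,
#'   `0 <= inner < outer`.
#' @return An `abluminal_band`: list with the ring, offsets, `band_area_um2`,
#'   and discretized `outer_polygon`/`inner_polygon` for QC rendering.
#' @export
build_abluminal_band <- function(ring, inner_offset_nm = 100,
                                 outer_offset_nm = 300) {
  if (!is.numeric(inner_offset_nm) || !is.numeric(outer_offset_nm) ||
      inner_offset_nm < 0 || outer_offset_nm <= inner_offset_nm)
    stop_tj("offsets must satisfy 0 <= inner < outer",
            class = "tjstorm_parameter_error")
  vx <- ring$vertices[, 1]; vy <- ring$vertices[, 2]
  if (!polygon_is_convex(vx, vy))
    stop_tj("ring polygon must be convex for outward offsetting; ",
            "use ring_from_localizations() or supply its convex hull",
            class = "tjstorm_geometry_error")
  per <- polygon_perimeter(vx, vy)
  area_nm2 <- per * (outer_offset_nm - inner_offset_nm) +
    pi * (outer_offset_nm^2 - inner_offset_nm^2)
  structure(list(
    ring = ring,
    inner_offset_nm = inner_offset_nm,
    outer_offset_nm = outer_offset_nm,
    band_area_um2 = area_nm2 / 1e6,
    outer_polygon = offset_convex_polygon(vx, vy, outer_offset_nm),
    inner_polygon = if (inner_offset_nm > 0)
      offset_convex_polygon(vx, vy, inner_offset_nm) else cbind(x = vx, y = vy)
  ), class = "abluminal_band")
}

#' @export
print.abluminal_band <- function(x, ...) {
  cat(sprintf("<abluminal_band> %g-%g nm outside ring '%s', area %.4f um^2\n",
              x$inner_offset_nm, x$outer_offset_nm, x$ring$label,
              x$band_area_um2))
  invisible(x)
}

#' Which points fall inside an abluminal band
#'
#' A point is in the band when it lies strictly outside the ring polygon and
#' its distance to the ring boundary is in `[inner_offset, outer_offset]`.
#'
#' @param band An `abluminal_band`.
#' @param x,y Point coordinates in nm.
#' @return Logical vector.
#' @export
points_in_band <- function(band, x, y) {
  if (!length(x)) return(logical(0))
  vx <- band$ring$vertices[, 1]; vy <- band$ring$vertices[, 2]
  outside <- !points_in_polygon(x, y, vx, vy)
  d <- points_polygon_boundary_distance(x, y, vx, vy)
  outside & d >= band$inner_offset_nm & d <= band$outer_offset_nm
}

#' Tracer density in the abluminal band
#'
#' @param tracer A [localization_table] of tracer signals in the same
#'   coordinate frame as the band.
#' @param band An `abluminal_band`.
#' @param capillary_id,group Identifiers carried into the output row.
#' @return One-row data frame: `capillary_id`, `group`, `tracer_channel`,
#'   `band_inner_nm`, `band_outer_nm`, `band_area_um2`, `tracer_count`,
#'   `density_per_um2` (relative index left `NA` until normalization).
#' @export
leakage_density <- function(tracer, band, capillary_id = "capillary",
                            group = "group") {
  cnt <- sum(points_in_band(band, tracer$x, tracer$y))
  data.frame(capillary_id = capillary_id, group = group,
             tracer_channel = channel_label(tracer),
             band_inner_nm = band$inner_offset_nm,
             band_outer_nm = band$outer_offset_nm,
             band_area_um2 = band$band_area_um2,
             tracer_count = cnt,
             density_per_um2 = cnt / band$band_area_um2,
             relative_index = NA_real_)
}

#' Normalize leakage densities to a reference group
#'
#' Divides every capillary's abluminal tracer density by the mean density of
#' the reference group, so the reference group's mean relative index equals
#' 1 by construction (its value defines the unit).
#'
#' @param records Data frame of [leakage_density()] rows (column
#'   `density_per_um2` and `group`).
#' @param reference_group Group label whose mean density defines index 1.
#' @return `records` with `relative_index` filled.
#' @export
relative_leakage_index <- function(records, reference_group) {
  ref <- records$density_per_um2[records$group == reference_group]
  if (!length(ref))
    stop_tj("reference group '", reference_group, "' has no records",
            class = "tjstorm_parameter_error")
  m <- mean(ref)
  if (!is.finite(m) || m <= 0)
    stop_tj("reference group mean density is zero; relative index undefined",
            class = "tjstorm_normalization_error")
  records$relative_index <- records$density_per_um2 / m
  attr(records, "reference_group") <- reference_group
  attr(records, "reference_mean_density") <- m
  records
}

#' Fit a convex claudin-5 ring from localizations
#'
#' Convenience for the auto-fit annotation route: the ring polygon is the
#' convex hull of the claudin-5 localizations in the cross-section.
#'
#' @param table A [localization_table] of the junctional channel.
#' @param label ROI label.
#' @return A convex [capillary_roi()].
#' @export
ring_from_localizations <- function(table, label = "claudin5-ring") {
  h <- convex_hull_ccw(table$x, table$y)
  if (is.null(h))
    stop_tj("localizations are degenerate (collinear or < 3 points); ",
            "cannot fit a ring", class = "tjstorm_geometry_error")
  capillary_roi(h, label = label)
}
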