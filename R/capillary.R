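# Per-capillary quantifications: total cellular signal within the annotated
# cross-section, capillary diameter, diameter-normalized abundance, clusters
# per capillary, and claudin-5 <-> ZO1 cluster-coupling classification.

#' Total cellular signal within a capillary ROI
#'
#' Counts the localizations lying inside or on the boundary of the
#' capillary cross-section polygon - the proxy for total cellular
#' expression of the labeled protein in that endothelial unit.
#'
#' @param table A [localization_table].
#' @param roi A [capillary_roi()].
#' @return Integer count.
#' @export
total_cellular_signal <- function(table, roi) {
  if (!nrow(table)) return(0L)
  sum(points_in_polygon(table$x, table$y,
                        roi$vertices[, 1], roi$vertices[, 2]))
}

#' Estimate capillary diameter from its ROI
#'
#' Capillary lumens are rarely circular in cross-section, so "diameter" is
#' an estimator convention. The default fits the ellipse matching the
#' polygon's area and central second-moment axis ratio and reports the mean
#' of its major and minor axis diameters. Alternatives: the equivalent-circle
#' diameter `2*sqrt(A/pi)` and the maximum Feret (caliper) diameter. All
#' three agree on circles up to polygonization error.
#'
#' @param roi A [capillary_roi()].
#' @param method `"ellipse"` (default), `"equivalent_circle"` or `"feret"`.
#' @return Diameter in micrometres.
#' @export
estimate_diameter <- function(roi, method = c("ellipse", "equivalent_circle",
                                              "feret")) {
  method <- match.arg(method)
  vx <- roi$vertices[, 1]; vy <- roi$vertices[, 2]
  a_nm2 <- polygon_area(vx, vy)
  if (a_nm2 <= 0)
    stop_tj("degenerate ROI polygon", class = "tjstorm_validation_error")
  d_nm <- switch(method,
    equivalent_circle = 2 * sqrt(a_nm2 / pi),
    feret = {
      h <- convex_hull_ccw(vx, vy)
      if (is.null(h)) stop_tj("degenerate ROI polygon",
                              class = "tjstorm_validation_error")
      max(stats::dist(h))
    },
    ellipse = {
      m <- polygon_second_moments(vx, vy)
      cov <- matrix(c(m$sxx, m$sxy, m$sxy, m$syy), 2)
      ev <- eigen(cov, symmetric = TRUE)$values
      ev[ev < 0] <- 0
      semi <- 2 * sqrt(ev)           # semi-axes of the moment-matched ellipse
      if (any(semi <= 0))
        stop_tj("degenerate ROI polygon", class = "tjstorm_validation_error")
      scl <- sqrt(a_nm2 / (pi * semi[1] * semi[2]))  # rescale to match area
      sum(2 * semi * scl) / 2        # mean of major and minor diameters
    })
  d_nm / 1e3
}

#' Diameter-normalized cellular signal
#'
#' Total signals per capillary divided by capillary diameter (signals/um).
#' Normalizing per-capillary totals to diameter makes capillaries of
#' different calibre comparable (larger vessels present more junctional
#' perimeter in a cross-section).
#'
#' @param total Signal count (>= 0).
#' @param diameter_um Capillary diameter in um (> 0).
#' @return Signals per micrometre.
#' @export
normalized_cellular_signal <- function(total, diameter_um) {
  if (!is.numeric(diameter_um) || any(diameter_um <= 0))
    stop_tj("diameter_um must be positive", class = "tjstorm_parameter_error")
  total / diameter_um
}

#' Clusters lying within a capillary ROI
#'
#' A cluster straddling the ROI boundary counts as inside iff its centroid
#' is inside (deterministic, order-free rule).
#'
#' @param properties A `cluster_properties` data frame.
#' @param roi A [capillary_roi()].
#' @return Logical vector over cluster rows.
#' @export
clusters_in_roi <- function(properties, roi) {
  if (!nrow(properties)) return(logical(0))
  points_in_polygon(properties$centroid_x_nm, properties$centroid_y_nm,
                    roi$vertices[, 1], roi$vertices[, 2])
}

#' Per-capillary metrics for one channel
#'
#' @param table A [localization_table] for the channel.
#' @param roi A [capillary_roi()].
#' @param properties Optional `cluster_properties` for the channel (to count
#'   non-degenerate clusters inside the ROI).
#' @param capillary_id Identifier for the output row.
#' @param diameter_method Passed to [estimate_diameter()].
#' @param normalize_by `"diameter"` (default) or `"perimeter"`: denominator
#'   of the normalized signal. Perimeter normalization approximates
#'   "per capillary circumference".
#' @return One-row data frame: `capillary_id`, `channel`, `diameter_um`,
#'   `perimeter_um`, `total_signals`, `normalized_signal_per_um`,
#'   `n_clusters`.
#' @export
capillary_metrics <- function(table, roi, properties = NULL,
                              capillary_id = roi$label,
                              diameter_method = "ellipse",
                              normalize_by = c("diameter", "perimeter")) {
  normalize_by <- match.arg(normalize_by)
  total <- total_cellular_signal(table, roi)
  diam <- estimate_diameter(roi, diameter_method)
  perim <- roi_perimeter_um(roi)
  denom <- if (normalize_by == "diameter") diam else perim
  ncl <- if (is.null(properties)) NA_integer_ else {
    inside <- clusters_in_roi(properties, roi)
    sum(inside & !properties$degenerate)
  }
  data.frame(capillary_id = capillary_id,
             channel = channel_label(table),
             diameter_um = diam,
             perimeter_um = perim,
             total_signals = total,
             normalized_signal_per_um = normalized_cellular_signal(total, denom),
             normalized_by = normalize_by,
             n_clusters = ncl)
}

#' Classify cluster coupling between two channels
#'
#' For each cluster of the primary channel (e.g. claudin-5), finds the
#' minimum member-to-member distance to any cluster of the partner channel
#' (e.g. ZO1). A primary cluster is "coupled" when that gap is at most
#' `pairing_nm`; otherwise it is "independent". The criterion is a package
#' convention (the coupling scale is of order 100 nm in junctional imagery)
#' and is echoed in all outputs.
#'
#' @param primary_props `cluster_properties` of the primary channel.
#' @param partner_props `cluster_properties` of the partner channel (may be
#'   empty: all primary clusters come back independent with infinite gap).
#' @param pairing_nm Coupling distance threshold in nm (> 0, default 100).
#' @return Data frame: `cluster_id`, `status` ("coupled"/"independent"),
#'   `partner_cluster_id` (`NA` when independent), `gap_nm`.
#' @export
pair_clusters <- function(primary_props, partner_props, pairing_nm = 100) {
  if (!is.numeric(pairing_nm) || pairing_nm <= 0)
    stop_tj("pairing_nm must be positive", class = "tjstorm_parameter_error")
  n <- nrow(primary_props)
  if (!n) {
    return(data.frame(cluster_id = integer(0), status = character(0),
                      partner_cluster_id = integer(0), gap_nm = numeric(0)))
  }
  np <- if (is.null(partner_props)) 0L else nrow(partner_props)
  gap <- rep(Inf, n)
  partner <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    a <- primary_props$members[[i]]
    for (j in seq_len(np)) {
      b <- partner_props$members[[j]]
      d <- min_cross_distance(a[, 1], a[, 2], b[, 1], b[, 2])
      if (d < gap[i]) {
        gap[i] <- d
        partner[i] <- partner_props$cluster_id[j]
      }
    }
  }
  coupled <- gap <= pairing_nm
  data.frame(cluster_id = primary_props$cluster_id,
             status = ifelse(coupled, "coupled", "independent"),
             partner_cluster_id = ifelse(coupled, partner, NA_integer_),
             gap_nm = gap)
}

#' Density contrast between coupled and independent clusters
#'
#' Mean and standard error of cluster density for the coupled and
#' independent groups, and their ratio (coupled / independent). Degenerate
#' clusters are excluded. An empty group is reported as absent and the
#' ratio flagged undefined rather than silently NaN.
#'
#' @param labels Output of [pair_clusters()].
#' @param props The matching primary-channel `cluster_properties`.
#' @return A list: per-group `n`, `mean_density`, `se_density`; `ratio`;
#'   `ratio_defined`.
#' @export
coupling_density_contrast <- function(labels, props) {
  if (!setequal(labels$cluster_id, props$cluster_id))
    stop_tj("labels and properties disagree on cluster ids",
            class = "tjstorm_consistency_error")
  dens <- props$density_per_um2[match(labels$cluster_id, props$cluster_id)]
  ok <- !props$degenerate[match(labels$cluster_id, props$cluster_id)] &
    !is.na(dens)
  grp <- function(status) {
    d <- dens[ok & labels$status == status]
    list(n = length(d),
         mean_density = if (length(d)) mean(d) else NA_real_,
         se_density = if (length(d) > 1) stats::sd(d) / sqrt(length(d))
                      else NA_real_)
  }
  co <- grp("coupled"); ind <- grp("independent")
  defined <- co$n > 0 && ind$n > 0 && ind$mean_density > 0
  list(coupled = co, independent = ind,
       ratio = if (defined) co$mean_density / ind$mean_density else NA_real_,
       ratio_defined = defined)
}
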