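# Distance-threshold cluster analysis of localization point patterns.
#
# The clustering rule is the strict single-linkage cut used throughout the
# quantifications: two localizations are "clustered" when their distance is
# smaller than the threshold (default 70 nm), and cluster membership is the
# transitive closure of that relation, so every localization belongs to
# exactly one cluster. Implementation uses grid-bucketed union-find in C++;
# the result is defined (and tested) to equal the brute-force all-pairs rule.

#' Partition localizations into distance-threshold clusters
#'
#' Two records share a cluster if and only if they are connected by a chain
#' of pairwise distances each strictly below `threshold_nm` (single-linkage
#' transitive closure). Points at exactly the threshold distance are never
#' merged. The partition is exhaustive and exclusive and is invariant under
#' record permutation up to relabeling; ids are contiguous `1..n_clusters`
#' in order of first appearance.
#'
#' @param table A [localization_table] (may be empty).
#' @param threshold_nm Distance threshold in nm, > 0. Default 70, the value
#'   used for all quantifications; thresholds in 50-100 nm give equivalent
#'   density results on junctional data.
#' @return A `cluster_partition`: list with `assignment` (integer per
#'   record), `threshold_nm` and `n_clusters`.
#' @export
#' @examples
#' tab <- localization_table(c(0, 0, 0), c(0, 65, 130), channel_label = "c5")
#' partition_localizations(tab, 70)$n_clusters  # chained into one cluster
partition_localizations <- function(table, threshold_nm = 70) {
  if (!is.numeric(threshold_nm) || length(threshold_nm) != 1L ||
      !is.finite(threshold_nm) || threshold_nm <= 0)
    stop_tj("threshold_nm must be a positive number",
            class = "tjstorm_parameter_error")
  assignment <- strict_linkage_components(as.numeric(table$x),
                                          as.numeric(table$y),
                                          threshold_nm)
  structure(list(assignment = assignment,
                 threshold_nm = threshold_nm,
                 n_clusters = if (length(assignment)) max(assignment) else 0L),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d records in %d clusters (threshold %g nm)\n",
              length(x$assignment), x$n_clusters, x$threshold_nm))
  invisible(x)
}

#' Per-cluster geometry and density
#'
#' For each cluster with at least `min_points` members, computes the signal
#' count, convex-hull area (um^2), signal density (count / area,
#' signals/um^2), centroid of member localizations, and the hull vertices
#' (counter-clockwise). Clusters whose members are fewer than 3 or collinear
#' have no well-defined hull area: they are flagged degenerate with area 0
#' and density `NA`, and are excluded from density summaries.
#'
#' @param table The clustered [localization_table].
#' @param partition The matching `cluster_partition`.
#' @param min_points Minimum member count to report a cluster (default 3,
#'   the smallest set with a non-degenerate hull).
#' @return A `cluster_properties` data frame with columns `cluster_id`,
#'   `n_points`, `area_um2`, `density_per_um2`, `centroid_x_nm`,
#'   `centroid_y_nm`, `degenerate`, plus list columns `hull` (two-column
#'   matrix, nm) and `members` (member coordinate matrix, nm).
#' @export
compute_cluster_properties <- function(table, partition, min_points = 3L) {
  if (length(partition$assignment) != nrow(table))
    stop_tj("partition and table have different record counts",
            class = "tjstorm_consistency_error")
  if (min_points < 1L)
    stop_tj("min_points must be >= 1", class = "tjstorm_parameter_error")
  ids <- sort(unique(partition$assignment))
  rows <- lapply(ids, function(id) {
    sel <- partition$assignment == id
    np <- sum(sel)
    if (np < min_points) return(NULL)
    mx <- table$x[sel]; my <- table$y[sel]
    hull <- convex_hull_ccw(mx, my)
    degenerate <- is.null(hull)
    area_nm2 <- if (degenerate) 0 else polygon_area(hull[, 1], hull[, 2])
    area_um2 <- area_nm2 / 1e6
    list(cluster_id = id, n_points = np, area_um2 = area_um2,
         density_per_um2 = if (degenerate) NA_real_ else np / area_um2,
         centroid_x_nm = mean(mx), centroid_y_nm = mean(my),
         degenerate = degenerate,
         hull = if (degenerate) cbind(x = mx, y = my) else hull,
         members = cbind(x = mx, y = my))
  })
  rows <- Filter(Negate(is.null), rows)
  df <- data.frame(
    cluster_id = vapply(rows, `[[`, integer(1), "cluster_id"),
    n_points = vapply(rows, `[[`, integer(1), "n_points"),
    area_um2 = vapply(rows, `[[`, numeric(1), "area_um2"),
    density_per_um2 = vapply(rows, `[[`, numeric(1), "density_per_um2"),
    centroid_x_nm = vapply(rows, `[[`, numeric(1), "centroid_x_nm"),
    centroid_y_nm = vapply(rows, `[[`, numeric(1), "centroid_y_nm"),
    degenerate = vapply(rows, `[[`, logical(1), "degenerate")
  )
  df$hull <- lapply(rows, `[[`, "hull")
  df$members <- lapply(rows, `[[`, "members")
  attr(df, "threshold_nm") <- partition$threshold_nm
  attr(df, "min_points") <- min_points
  class(df) <- c("cluster_properties", "data.frame")
  df
}

#' Sweep the clustering threshold
#'
#' Repartitions the table at each threshold (ascending) and summarizes mean
#' cluster density. Because single linkage is monotone in the threshold,
#' each partition refines the next: growing the threshold can only merge
#' clusters, never split them. Used to establish that densities are robust
#' across the 50-100 nm admissible range.
#'
#' @param table A [localization_table].
#' @param thresholds_nm Strictly ascending positive thresholds (nm).
#' @param min_points Passed to [compute_cluster_properties()].
#' @return A list with `summary` (data frame: threshold_nm, n_clusters,
#'   mean_density_per_um2, se_density) and `partitions` (list of
#'   `cluster_partition`).
#' @export
threshold_sweep <- function(table, thresholds_nm = c(50, 60, 70, 80, 90, 100),
                            min_points = 3L) {
  if (any(thresholds_nm <= 0) || is.unsorted(thresholds_nm, strictly = TRUE))
    stop_tj("thresholds_nm must be positive and strictly ascending",
            class = "tjstorm_parameter_error")
  partitions <- lapply(thresholds_nm, function(t) partition_localizations(table, t))
  rows <- lapply(seq_along(thresholds_nm), function(i) {
    props <- compute_cluster_properties(table, partitions[[i]], min_points)
    s <- cluster_summary(props)
    data.frame(threshold_nm = thresholds_nm[i],
               n_clusters = s$n_clusters,
               mean_density_per_um2 = s$mean_density,
               se_density = s$se_density)
  })
  list(summary = do.call(rbind, rows), partitions = partitions)
}

#' Summarize a set of cluster properties
#'
#' Cluster count, binned histograms of cluster area and of signals per
#' cluster, and mean with standard error of density over non-degenerate
#' clusters. Default area bin edges include 0.1 and 0.3 um^2, the
#' boundaries used when describing shifts toward smaller clusters.
#'
#' @param properties A `cluster_properties` data frame.
#' @param area_breaks_um2 Area histogram edges (um^2); values beyond the
#'   last edge fall in an overflow bin.
#' @param points_breaks Signals-per-cluster histogram edges.
#' @return A list: `n_clusters`, `n_degenerate`, `area_hist`, `points_hist`
#'   (data frames with `lower`, `upper`, `count`), `mean_density`,
#'   `se_density`, `n_density` (clusters entering the density summary).
#' @export
cluster_summary <- function(properties,
                            area_breaks_um2 = c(0, 0.1, 0.3, 0.5, 1, 2),
                            points_breaks = c(0, 10, 50, 100, 500, 1000, 5000)) {
  binned <- function(v, edges) {
    edges <- c(edges, Inf)
    idx <- findInterval(v, edges, left.open = FALSE, rightmost.closed = FALSE)
    data.frame(lower = edges[-length(edges)], upper = edges[-1],
               count = tabulate(idx, nbins = length(edges) - 1L))
  }
  n <- nrow(properties) %||% 0L
  if (!n) {
    return(list(n_clusters = 0L, n_degenerate = 0L,
                area_hist = binned(numeric(0), area_breaks_um2),
                points_hist = binned(numeric(0), points_breaks),
                mean_density = NA_real_, se_density = NA_real_,
                n_density = 0L))
  }
  dens <- properties$density_per_um2[!properties$degenerate]
  list(n_clusters = n,
       n_degenerate = sum(properties$degenerate),
       area_hist = binned(properties$area_um2[!properties$degenerate],
                          area_breaks_um2),
       points_hist = binned(properties$n_points, points_breaks),
       mean_density = if (length(dens)) mean(dens) else NA_real_,
       se_density = if (length(dens) > 1) stats::sd(dens) / sqrt(length(dens))
                    else NA_real_,
       n_density = length(dens))
}

#' Export cluster properties as a plain table
#'
#' Drops the list columns so the result can be written with
#' [utils::write.csv()]; the per-record partition can be appended to the
#' molecular list via `cbind(table, cluster_id = partition$assignment)`.
#'
#' @param properties A `cluster_properties` data frame.
#' @return A plain data frame.
#' @export
cluster_table <- function(properties) {
  df <- as.data.frame(properties)
  df$hull <- NULL
  df$members <- NULL
  df
}
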