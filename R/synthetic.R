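# Synthetic SMLM scene generator with ground truth.
#
# Generation is a Neyman-Scott compound process mimicking how dSTORM data
# arise: cluster centers are placed on a chosen geometry (capillary ring
# circumference, linear strand, or dispersed in the field); each cluster
# holds a random number of true molecules spread around the center; each
# molecule emits a random number >= 1 of blinks (antibody/fluorophore
# overcounting: every resolved signal is an amplified proxy of the target),
# each displaced by the localization precision. Background and tracer points
# are homogeneous Poisson fields. Every localization traces back to its
# molecule, cluster or field of origin, which is what makes planted-
# parameter recovery testable.

# zero-truncated Poisson (support >= 1), by redrawing zeros
.rztpois <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  for (iter in 1:1000) {
    z <- x == 0L
    if (!any(z)) break
    x[z] <- stats::rpois(sum(z), lambda)
  }
  x[x == 0L] <- 1L
  x
}

# geometric on {1, 2, ...} with mean b (blinks per molecule)
.rblinks <- function(n, mean_blinks) {
  if (mean_blinks <= 1) return(rep(1L, n))
  stats::rgeom(n, prob = 1 / mean_blinks) + 1L
}

#' Configure a synthetic localization scene
#'
#' Defaults describe a postnatal-like capillary cross-section: a 5.9 um
#' diameter ring carrying discrete junctional clusters, ~20 nm localization
#' precision, and 3-fold blink/label overcounting. See [scene_preset()] for
#' the named regimes.
#'
#' @param geometry `"ring"` (cluster centers on a capillary ring
#'   circumference), `"strand"` (on a line segment) or `"dispersed"`
#'   (uniform in the field).
#' @param ring_diameter_um Ring diameter (also the strand length), um.
#' @param n_clusters Number of planted clusters.
#' @param molecules_per_cluster Mean of the zero-truncated Poisson molecule
#'   count per cluster.
#' @param cluster_radius_nm Spatial spread of true molecule positions
#'   (Gaussian sd, or disc radius when `cluster_shape = "disc"`). Scalar or
#'   vector recycled over clusters.
#' @param blinks_per_molecule Mean of the geometric (>= 1) blink count.
#' @param sigma_loc_nm Localization precision (Gaussian sd per blink), nm.
#' @param background_rate_um2 Dispersed background localizations per um^2.
#' @param cluster_shape `"gaussian"` or `"disc"` molecule placement.
#' @param cluster_spacing `"uniform"` (random positions on the geometry) or
#'   `"even"` (equally spaced with a random rotation/offset - the
#'   well-separated regime used for recovery guarantees).
#' @param tracer Optional `list(luminal_density_um2, abluminal_density_um2,
#'   band_nm = c(100, 300))` adding a tracer channel: a Poisson field in the
#'   lumen plus one in the abluminal annulus. Requires `geometry = "ring"`.
#' @param partner Optional `list(channel_label = "zo1", coupled_fraction,
#'   gap_nm = 50, cluster_radius_nm, molecules_per_cluster)` adding a
#'   partner channel whose clusters sit next to the first
#'   `round(coupled_fraction * n_clusters)` primary clusters.
#' @param channel_label Label of the clustered channel.
#' @param seed Integer seed fixing the full output.
#' @return A `scene_config` list.
#' @export
scene_config <- function(geometry = c("ring", "strand", "dispersed"),
                         ring_diameter_um = 5.9,
                         n_clusters = 12L,
                         molecules_per_cluster = 100,
                         cluster_radius_nm = 300,
                         blinks_per_molecule = 3,
                         sigma_loc_nm = 20,
                         background_rate_um2 = 0,
                         cluster_shape = c("disc", "gaussian"),
                         cluster_spacing = c("uniform", "even"),
                         tracer = NULL,
                         partner = NULL,
                         channel_label = "claudin5",
                         seed = 1L) {
  geometry <- match.arg(geometry)
  cluster_shape <- match.arg(cluster_shape)
  cluster_spacing <- match.arg(cluster_spacing)
  if (sigma_loc_nm <= 0)
    stop_tj("sigma_loc_nm must be positive", class = "tjstorm_config_error")
  if (any(c(ring_diameter_um, molecules_per_cluster, blinks_per_molecule) <= 0) ||
      n_clusters < 0 || background_rate_um2 < 0 || any(cluster_radius_nm < 0))
    stop_tj("rates, means and sizes must be non-negative",
            class = "tjstorm_config_error")
  if (!is.null(tracer) && geometry != "ring")
    stop_tj("tracer fields need a ring geometry (a lumen to leak from)",
            class = "tjstorm_config_error")
  if (!is.null(tracer)) {
    tracer$band_nm <- tracer$band_nm %||% c(100, 300)
    tracer$luminal_density_um2 <- tracer$luminal_density_um2 %||% 0
    tracer$abluminal_density_um2 <- tracer$abluminal_density_um2 %||% 0
  }
  if (!is.null(partner)) {
    partner$channel_label <- partner$channel_label %||% "zo1"
    partner$coupled_fraction <- partner$coupled_fraction %||% 0.5
    partner$gap_nm <- partner$gap_nm %||% 50
    partner$cluster_radius_nm <- partner$cluster_radius_nm %||%
      cluster_radius_nm[1]
    partner$molecules_per_cluster <- partner$molecules_per_cluster %||%
      molecules_per_cluster
  }
  structure(list(geometry = geometry, ring_diameter_um = ring_diameter_um,
                 n_clusters = as.integer(n_clusters),
                 molecules_per_cluster = molecules_per_cluster,
                 cluster_radius_nm = cluster_radius_nm,
                 blinks_per_molecule = blinks_per_molecule,
                 sigma_loc_nm = sigma_loc_nm,
                 background_rate_um2 = background_rate_um2,
                 cluster_shape = cluster_shape,
                 cluster_spacing = cluster_spacing,
                 tracer = tracer, partner = partner,
                 channel_label = channel_label,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Named scene presets
#'
#' Illustrative regimes, not claims about any real dataset:
#' `"P9"` - mature cross-section: 5.9 um ring, 12 discrete dense clusters;
#' `"E12"` - embryonic-like: 11.1 um ring, ~2.6x more, smaller-gap clusters;
#' `"occludin"` - dispersed, background-dominated organization.
#'
#' @param name Preset name.
#' @param seed Seed.
#' @param ... Overrides passed to [scene_config()].
#' @return A `scene_config`.
#' @export
scene_preset <- function(name = c("P9", "E12", "occludin"), seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    P9 = list(geometry = "ring", ring_diameter_um = 5.9, n_clusters = 12L,
              molecules_per_cluster = 100, cluster_radius_nm = 330,
              blinks_per_molecule = 3, background_rate_um2 = 2),
    E12 = list(geometry = "ring", ring_diameter_um = 11.1, n_clusters = 31L,
               molecules_per_cluster = 145, cluster_radius_nm = 310,
               blinks_per_molecule = 3, background_rate_um2 = 2),
    occludin = list(geometry = "dispersed", ring_diameter_um = 5.9,
                    n_clusters = 4L, molecules_per_cluster = 30,
                    cluster_radius_nm = 150, blinks_per_molecule = 3,
                    background_rate_um2 = 60))
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(scene_config, args)
}

# cluster centers on the configured geometry, within a field of side `side`
.place_centers <- function(config, center, radius_nm) {
  n <- config$n_clusters
  if (!n) return(cbind(x = numeric(0), y = numeric(0)))
  if (config$geometry == "ring") {
    theta <- if (config$cluster_spacing == "even")
      stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(n) - 1L) / n
    else stats::runif(n, 0, 2 * pi)
    cbind(x = center[1] + radius_nm * cos(theta),
          y = center[2] + radius_nm * sin(theta))
  } else if (config$geometry == "strand") {
    len <- 2 * radius_nm
    s <- if (config$cluster_spacing == "even")
      len * (seq_len(n) - 0.5) / n else stats::runif(n, 0, len)
    cbind(x = center[1] - radius_nm + s, y = rep(center[2], n))
  } else {
    side <- 2 * (radius_nm + 1000)
    cbind(x = center[1] + stats::runif(n, -side / 2, side / 2),
          y = center[2] + stats::runif(n, -side / 2, side / 2))
  }
}

.spawn_cluster_channel <- function(centers, radii, mol_mean, blink_mean,
                                   sigma, shape, channel_label,
                                   molecule_id0 = 0L) {
  n <- nrow(centers)
  mols <- list(); locs <- list()
  mid <- molecule_id0
  for (i in seq_len(n)) {
    m <- .rztpois(1L, mol_mean)
    if (shape == "disc") {
      r <- radii[i] * sqrt(stats::runif(m))
      a <- stats::runif(m, 0, 2 * pi)
      mx <- centers[i, 1] + r * cos(a)
      my <- centers[i, 2] + r * sin(a)
    } else {
      mx <- stats::rnorm(m, centers[i, 1], radii[i])
      my <- stats::rnorm(m, centers[i, 2], radii[i])
    }
    blinks <- .rblinks(m, blink_mean)
    ids <- mid + seq_len(m)
    mid <- mid + m
    mols[[i]] <- data.frame(molecule_id = ids, cluster_id = i,
                            x = mx, y = my, n_blinks = blinks)
    rep_idx <- rep(seq_len(m), blinks)
    locs[[i]] <- data.frame(
      x = mx[rep_idx] + stats::rnorm(sum(blinks), 0, sigma),
      y = my[rep_idx] + stats::rnorm(sum(blinks), 0, sigma),
      molecule_id = ids[rep_idx], cluster_id = i)
  }
  list(molecules = do.call(rbind, mols) %||%
         data.frame(molecule_id = integer(0), cluster_id = integer(0),
                    x = numeric(0), y = numeric(0), n_blinks = integer(0)),
       locs = do.call(rbind, locs) %||%
         data.frame(x = numeric(0), y = numeric(0),
                    molecule_id = integer(0), cluster_id = integer(0)))
}

#' Generate a synthetic SMLM scene
#'
#' Fully reproducible from `config$seed`; the caller's RNG state is left
#' untouched. See [scene_config()] for the generative model.
#'
#' @param config A [scene_config()].
#' @return An `smlm_scene`: list with `channels` (named
#'   [localization_table]s), `truth` (molecule table, planted cluster table
#'   with true-membership hull areas and densities, per-localization
#'   lineage, tracer classes) and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    ring_r <- config$ring_diameter_um * 1e3 / 2
    spread <- max(config$cluster_radius_nm, 1) + 5 * config$sigma_loc_nm
    margin <- spread + 1e3
    side <- 2 * (ring_r + margin)
    center <- c(side / 2, side / 2)
    radii <- rep_len(config$cluster_radius_nm, max(config$n_clusters, 1L))

    centers <- .place_centers(config, center, ring_r)
    ch <- .spawn_cluster_channel(centers, radii,
                                 config$molecules_per_cluster,
                                 config$blinks_per_molecule,
                                 config$sigma_loc_nm, config$cluster_shape,
                                 config$channel_label)
    # background field over the whole scene
    area_um2 <- (side / 1e3)^2
    nbg <- stats::rpois(1L, config$background_rate_um2 * area_um2)
    bg <- data.frame(x = stats::runif(nbg, 0, side),
                     y = stats::runif(nbg, 0, side),
                     molecule_id = rep(NA_integer_, nbg),
                     cluster_id = rep(NA_integer_, nbg))
    main <- rbind(ch$locs, bg)
    source <- c(rep("cluster", nrow(ch$locs)), rep("background", nbg))
    channels <- list()
    channels[[config$channel_label]] <- localization_table(
      main$x, main$y, uncertainty = rep(config$sigma_loc_nm, nrow(main)),
      channel_label = config$channel_label)

    # planted per-cluster truth, under the same hull-area convention the
    # pipeline uses, computed from true membership
    planted <- lapply(seq_len(nrow(centers)), function(i) {
      sel <- ch$locs$cluster_id == i
      np <- sum(sel)
      hull <- if (np >= 3) convex_hull_ccw(ch$locs$x[sel], ch$locs$y[sel]) else NULL
      area <- if (is.null(hull)) NA_real_
        else polygon_area(hull[, 1], hull[, 2]) / 1e6
      data.frame(cluster_id = i, center_x = centers[i, 1],
                 center_y = centers[i, 2],
                 n_molecules = sum(ch$molecules$cluster_id == i),
                 n_localizations = np,
                 planted_area_um2 = area,
                 planted_density_per_um2 = if (is.na(area) || area <= 0)
                   NA_real_ else np / area)
    })
    planted <- do.call(rbind, planted) %||%
      data.frame(cluster_id = integer(0))

    # partner channel: clusters adjacent to the first coupled_fraction of
    # primary clusters
    partner_truth <- NULL
    if (!is.null(config$partner) && nrow(centers)) {
      pc <- config$partner
      ncoup <- round(pc$coupled_fraction * nrow(centers))
      planted$coupled <- seq_len(nrow(planted)) <= ncoup
      if (ncoup > 0) {
        ang <- stats::runif(ncoup, 0, 2 * pi)
        pcenters <- cbind(x = centers[seq_len(ncoup), 1] + pc$gap_nm * cos(ang),
                          y = centers[seq_len(ncoup), 2] + pc$gap_nm * sin(ang))
        pch <- .spawn_cluster_channel(pcenters,
                                      rep_len(pc$cluster_radius_nm, ncoup),
                                      pc$molecules_per_cluster,
                                      config$blinks_per_molecule,
                                      config$sigma_loc_nm,
                                      config$cluster_shape,
                                      pc$channel_label)
        channels[[pc$channel_label]] <- localization_table(
          pch$locs$x, pch$locs$y,
          uncertainty = rep(config$sigma_loc_nm, nrow(pch$locs)),
          channel_label = pc$channel_label)
        partner_truth <- list(molecules = pch$molecules,
                              lineage = pch$locs[c("molecule_id", "cluster_id")])
      } else {
        channels[[pc$channel_label]] <- localization_table(
          numeric(0), numeric(0), channel_label = pc$channel_label)
      }
    }

    # tracer fields: lumen disc + abluminal annulus around the ring
    tracer_truth <- NULL
    if (!is.null(config$tracer)) {
      tr <- config$tracer
      lum_area <- pi * ring_r^2 / 1e6
      nlum <- stats::rpois(1L, tr$luminal_density_um2 * lum_area)
      rl <- ring_r * sqrt(stats::runif(nlum))
      al <- stats::runif(nlum, 0, 2 * pi)
      r0 <- ring_r + tr$band_nm[1]
      r1 <- ring_r + tr$band_nm[2]
      ab_area <- pi * (r1^2 - r0^2) / 1e6
      nab <- stats::rpois(1L, tr$abluminal_density_um2 * ab_area)
      ra <- sqrt(stats::runif(nab, r0^2, r1^2))
      aa <- stats::runif(nab, 0, 2 * pi)
      channels[["tracer"]] <- localization_table(
        x = c(center[1] + rl * cos(al), center[1] + ra * cos(aa)),
        y = c(center[2] + rl * sin(al), center[2] + ra * sin(aa)),
        channel_label = "tracer")
      tracer_truth <- data.frame(
        class = c(rep("luminal", nlum), rep("abluminal", nab)))
    }

    structure(list(
      channels = channels,
      truth = list(molecules = ch$molecules,
                   clusters = planted,
                   lineage = data.frame(source = source,
                                        molecule_id = main$molecule_id,
                                        cluster_id = main$cluster_id),
                   partner = partner_truth,
                   tracer = tracer_truth,
                   field_side_nm = side,
                   ring_center_nm = center,
                   ring_radius_nm = if (config$geometry == "ring") ring_r else NA_real_),
      config = config), class = "smlm_scene")
  })
}

#' @export
print.smlm_scene <- function(x, ...) {
  cat(sprintf("<smlm_scene> seed %d, %s geometry; channels: %s\n",
              x$config$seed, x$config$geometry,
              paste(sprintf("%s (%d)", names(x$channels),
                            vapply(x$channels, nrow, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Capillary ring ROI of a scene
#'
#' The planted ring circle, polygonized, for use as the capillary
#' cross-section / claudin-5 ring annotation of the synthetic capillary.
#'
#' @param scene An `smlm_scene` with ring geometry.
#' @param n_vertices Polygonization resolution.
#' @param label ROI label.
#' @return A [capillary_roi()].
#' @export
scene_ring_roi <- function(scene, n_vertices = 256L, label = "synthetic-ring") {
  if (scene$config$geometry != "ring")
    stop_tj("scene has no ring", class = "tjstorm_config_error")
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  capillary_roi(cbind(scene$truth$ring_center_nm[1] +
                        scene$truth$ring_radius_nm * cos(th),
                      scene$truth$ring_center_nm[2] +
                        scene$truth$ring_radius_nm * sin(th)),
                label = label)
}

# Hubert-Arabie adjusted Rand index between two labelings
.adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}

#' Compare a recovered partition with the planted truth
#'
#' @param scene The generating `smlm_scene`.
#' @param partition A `cluster_partition` of the scene's clustered channel.
#' @param min_points Cluster size cutoff used for the property-based
#'   summaries (as in [compute_cluster_properties()]).
#' @return A list: `planted_n_clusters`, `recovered_n_clusters` (all
#'   recovered components), `recovered_n_clusters_min_points`, `ari`
#'   (adjusted Rand index over cluster-derived localizations),
#'   `mean_planted_density`, `mean_recovered_density`,
#'   `density_relative_error`.
#' @export
planted_recovery_report <- function(scene, partition, min_points = 3L) {
  tab <- scene$channels[[scene$config$channel_label]]
  if (length(partition$assignment) != nrow(tab))
    stop_tj("partition does not match the scene's clustered channel",
            class = "tjstorm_consistency_error")
  lin <- scene$truth$lineage
  is_cluster <- lin$source == "cluster"
  ari <- if (any(is_cluster))
    .adjusted_rand_index(lin$cluster_id[is_cluster],
                         partition$assignment[is_cluster]) else NA_real_
  props <- compute_cluster_properties(tab, partition, min_points)
  rec_dens <- props$density_per_um2[!props$degenerate]
  planted_dens <- scene$truth$clusters$planted_density_per_um2
  planted_dens <- planted_dens[is.finite(planted_dens)]
  mp <- if (length(planted_dens)) mean(planted_dens) else NA_real_
  mr <- if (length(rec_dens)) mean(rec_dens) else NA_real_
  list(planted_n_clusters = sum(scene$truth$clusters$n_localizations > 0),
       recovered_n_clusters = partition$n_clusters,
       recovered_n_clusters_min_points = nrow(props),
       ari = ari,
       mean_planted_density = mp,
       mean_recovered_density = mr,
       density_relative_error = if (is.finite(mp) && mp > 0)
         abs(mr - mp) / mp else NA_real_)
}

#' Write a scene to disk
#'
#' Emits one molecular-list CSV per channel, the ring ROI (if any) as JSON,
#' a ground-truth sidecar JSON and the full config for provenance.
#'
#' @param scene An `smlm_scene`.
#' @param dir Output directory (created if needed).
#' @param dialect CSV dialect for the molecular lists.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, dialect = molecular_list_dialect()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scene$channels))
    write_molecular_list(scene$channels[[nm]],
                         file.path(dir, paste0(nm, ".csv")), dialect)
  if (scene$config$geometry == "ring")
    write_roi(scene_ring_roi(scene), file.path(dir, "ring.json"))
  jsonlite::write_json(
    list(config = unclass(scene$config),
         clusters = scene$truth$clusters,
         molecules = scene$truth$molecules,
         lineage = scene$truth$lineage,
         tracer = scene$truth$tracer),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
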