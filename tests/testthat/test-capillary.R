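test_that("total cellular signal: containment, additivity, oracle", {
  set.seed(12)
  tab <- random_table(500, extent_nm = 8000)
  x0 <- min(tab$x) - 1; x1 <- max(tab$x) + 1
  y0 <- min(tab$y) - 1; y1 <- max(tab$y) + 1
  all_roi <- capillary_roi(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
  expect_equal(total_cellular_signal(tab, all_roi), 500L)

  far <- capillary_roi(rbind(c(2e4, 2e4), c(3e4, 2e4), c(3e4, 3e4)))
  expect_equal(total_cellular_signal(tab, far), 0L)

  roi <- circle_roi(2500, center = c(4000, 4000))
  got <- total_cellular_signal(tab, roi)
  expect_equal(got, sum(oracle_in_polygon(tab$x, tab$y,
                                          roi$vertices[, 1],
                                          roi$vertices[, 2])))
  # additive over disjoint halves, monotone under containment
  left <- capillary_roi(rbind(c(x0, y0), c(3999.5, y0), c(3999.5, y1),
                              c(x0, y1)))
  right <- capillary_roi(rbind(c(4000.5, y0), c(x1, y0), c(x1, y1),
                               c(4000.5, y1)))
  inner <- circle_roi(1000, center = c(4000, 4000))
  expect_equal(total_cellular_signal(tab, left) +
                 total_cellular_signal(tab, right),
               sum(tab$x < 3999.5 | tab$x > 4000.5))
  expect_lte(total_cellular_signal(tab, inner), got)
})

test_that("diameter estimators: circle agreement, moments oracle, scaling", {
  roi <- circle_roi(2950, n = 256)
  for (m in c("ellipse", "equivalent_circle", "feret"))
    expect_equal(estimate_diameter(roi, m), 5.9, tolerance = 0.005)

  # 10 x 4 um rectangle vs closed-form rectangle moments
  rect <- capillary_roi(rbind(c(0, 0), c(1e4, 0), c(1e4, 4e3), c(0, 4e3)))
  w <- 1e4; h <- 4e3
  a <- 2 * sqrt(w^2 / 12); b <- 2 * sqrt(h^2 / 12)    # moment-matched axes
  s <- sqrt(w * h / (pi * a * b))                     # rescaled to the area
  expect_equal(estimate_diameter(rect, "ellipse"), s * (a + b) / 1e3,
               tolerance = 1e-9)
  expect_equal(estimate_diameter(rect, "feret"),
               sqrt(w^2 + h^2) / 1e3, tolerance = 1e-9)

  # homogeneity: scaling vertices x2 doubles every estimator
  rect2 <- capillary_roi(rect$vertices * 2)
  for (m in c("ellipse", "equivalent_circle", "feret"))
    expect_equal(estimate_diameter(rect2, m), 2 * estimate_diameter(rect, m),
                 tolerance = 1e-12)
})

test_that("normalized cellular signal", {
  expect_equal(normalized_cellular_signal(14341, 11.1), 1292.0,
               tolerance = 1e-4)
  expect_equal(normalized_cellular_signal(3590, 5.9), 608.5,
               tolerance = 1e-4)
  expect_equal(normalized_cellular_signal(0, 5.9), 0)
  expect_error(normalized_cellular_signal(10, 0),
               class = "tjstorm_parameter_error")
  # scale consistency: doubling the diameter halves it at fixed total
  expect_equal(normalized_cellular_signal(100, 10),
               normalized_cellular_signal(100, 5) / 2)
})

test_that("capillary metrics are internally consistent", {
  set.seed(31)
  sc <- generate_scene(scene_preset("P9", seed = 31))
  tab <- sc$channels$claudin5
  roi <- scene_ring_roi(sc)
  # ring ROI traces the claudin ring; enlarge to cover the cluster band
  big <- capillary_roi(
    (roi$vertices - rep(colMeans(roi$vertices), each = nrow(roi$vertices))) *
      1.4 + rep(colMeans(roi$vertices), each = nrow(roi$vertices)))
  props <- compute_cluster_properties(tab, partition_localizations(tab, 70))
  m <- capillary_metrics(tab, big, props, capillary_id = "cap1")
  expect_equal(m$normalized_signal_per_um * m$diameter_um, m$total_signals,
               tolerance = 1e-6)
  expect_lte(m$n_clusters, nrow(props))
  inside <- clusters_in_roi(props, big)
  expect_equal(m$n_clusters, sum(inside & !props$degenerate))
  # sum of member counts of in-ROI clusters cannot exceed the total
  expect_lte(sum(props$n_points[inside]), m$total_signals +
               sum(!points_in_polygon(tab$x, tab$y, big$vertices[, 1],
                                      big$vertices[, 2])))
  mp <- capillary_metrics(tab, big, props, normalize_by = "perimeter")
  expect_equal(mp$normalized_signal_per_um * mp$perimeter_um,
               mp$total_signals, tolerance = 1e-6)
})

test_that("cluster coupling: fixtures, oracle, symmetry", {
  mk_props <- function(coords_list) {
    if (!length(coords_list)) {
      df <- data.frame(cluster_id = integer(0), n_points = integer(0),
                       area_um2 = numeric(0), density_per_um2 = numeric(0),
                       centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
                       degenerate = logical(0))
      df$members <- list(); df$hull <- list()
      class(df) <- c("cluster_properties", "data.frame")
      return(df)
    }
    df <- data.frame(
      cluster_id = seq_along(coords_list),
      n_points = vapply(coords_list, nrow, integer(1)),
      area_um2 = 1, density_per_um2 = 1,
      centroid_x_nm = vapply(coords_list, function(m) mean(m[, 1]), 0),
      centroid_y_nm = vapply(coords_list, function(m) mean(m[, 2]), 0),
      degenerate = FALSE)
    df$members <- coords_list
    df$hull <- coords_list
    class(df) <- c("cluster_properties", "data.frame")
    df
  }
  a <- mk_props(list(cbind(c(0, 10), c(0, 0))))
  b_shared <- mk_props(list(cbind(c(10, 500), c(0, 0))))
  lab <- pair_clusters(a, b_shared, 100)
  expect_equal(lab$gap_nm, 0)
  expect_equal(lab$status, "coupled")
  expect_equal(lab$partner_cluster_id, 1L)

  b_far <- mk_props(list(cbind(c(1010, 1020), c(0, 0))))
  lab2 <- pair_clusters(a, b_far, 100)
  expect_equal(lab2$status, "independent")
  expect_equal(lab2$gap_nm, 1000)
  expect_true(is.na(lab2$partner_cluster_id))

  # empty partner list: independent with infinite gap
  lab3 <- pair_clusters(a, mk_props(list()), 100)
  expect_equal(lab3$status, "independent")
  expect_equal(lab3$gap_nm, Inf)

  # randomized scene equals the brute-force oracle, both directions
  set.seed(55)
  ta <- random_table(150, extent_nm = 3000)
  tb <- random_table(150, extent_nm = 3000, label = "zo1")
  pa <- compute_cluster_properties(ta, partition_localizations(ta, 70))
  pb <- compute_cluster_properties(tb, partition_localizations(tb, 70))
  la <- pair_clusters(pa, pb, 100)
  expect_equal(la$gap_nm, oracle_pair_gaps(pa, pb))
  lb <- pair_clusters(pb, pa, 100)
  expect_equal(lb$gap_nm, oracle_pair_gaps(pb, pa))
  # geometric symmetry: if A couples to B with gap g, B's gap to A's
  # channel is at most g (A itself realizes it)
  for (i in which(la$status == "coupled")) {
    j <- match(la$partner_cluster_id[i], lb$cluster_id)
    expect_lte(lb$gap_nm[j], la$gap_nm[i] + 1e-9)
  }
})

test_that("coupling density contrast: arithmetic, empty group, recovery", {
  props <- data.frame(cluster_id = 1:4, n_points = 10L, area_um2 = 1,
                      density_per_um2 = c(200, 400, 100, 100),
                      centroid_x_nm = 0, centroid_y_nm = 0,
                      degenerate = FALSE)
  class(props) <- c("cluster_properties", "data.frame")
  labels <- data.frame(cluster_id = 1:4,
                       status = c("coupled", "coupled", "independent",
                                  "independent"),
                       partner_cluster_id = c(1L, 2L, NA, NA),
                       gap_nm = c(0, 0, Inf, Inf))
  cc <- coupling_density_contrast(labels, props)
  expect_equal(cc$ratio, 3)
  expect_true(cc$ratio_defined)

  all_coupled <- labels
  all_coupled$status <- "coupled"
  cc2 <- coupling_density_contrast(all_coupled, props)
  expect_false(cc2$ratio_defined)
  expect_true(is.na(cc2$ratio))
  expect_equal(cc2$independent$n, 0L)

  expect_error(coupling_density_contrast(labels[1:3, ], props),
               class = "tjstorm_consistency_error")

  # planted 5x contrast: coupled clusters denser by 5 (disc radius / sqrt(5))
  sc <- generate_scene(scene_config(
    geometry = "ring", ring_diameter_um = 11.1, n_clusters = 16,
    cluster_spacing = "even", cluster_shape = "disc",
    cluster_radius_nm = c(rep(300 / sqrt(5), 8), rep(300, 8)),
    molecules_per_cluster = 250, background_rate_um2 = 0,
    sigma_loc_nm = 1,   # negligible blur so the geometric 5x ratio is exact
    partner = list(channel_label = "zo1", coupled_fraction = 0.5,
                   gap_nm = 30, cluster_radius_nm = 100),
    seed = 77))
  tab <- sc$channels$claudin5
  props5 <- compute_cluster_properties(tab, partition_localizations(tab, 70))
  partner_tab <- sc$channels$zo1
  partner_props <- compute_cluster_properties(
    partner_tab, partition_localizations(partner_tab, 70))
  lab5 <- pair_clusters(props5, partner_props, 100)
  cc5 <- coupling_density_contrast(lab5, props5)
  se <- ratio_se(props5$density_per_um2[lab5$status == "coupled"],
                 props5$density_per_um2[lab5$status == "independent"])
  expect_lt(abs(cc5$ratio - 5), 3 * se)
})
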