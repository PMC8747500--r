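test_that("strict threshold semantics and chaining", {
  two <- localization_table(c(0, 0, 0), c(0, 60, 130), channel_label = "c5")
  expect_equal(partition_localizations(two, 70)$n_clusters, 2L)
  expect_equal(canonical_labels(partition_localizations(two, 70)$assignment),
               c(1L, 1L, 2L))

  one <- localization_table(c(0, 0, 0), c(0, 65, 130), channel_label = "c5")
  expect_equal(partition_localizations(one, 70)$n_clusters, 1L)

  # distance exactly at the threshold never merges
  at <- localization_table(c(0, 0), c(0, 70), channel_label = "c5")
  expect_equal(partition_localizations(at, 70)$n_clusters, 2L)

  expect_error(partition_localizations(two, 0),
               class = "tjstorm_parameter_error")
  empty <- localization_table(numeric(0), numeric(0), channel_label = "c5")
  expect_equal(partition_localizations(empty, 70)$n_clusters, 0L)
})

test_that("partition equals all-pairs oracles and is order-invariant", {
  set.seed(42)
  for (rep in 1:25) {
    tab <- random_table(sample(20:300, 1))
    t_nm <- sample(c(50, 70, 100), 1)
    part <- partition_localizations(tab, t_nm)
    oracle <- oracle_partition(tab$x, tab$y, t_nm)
    expect_equal(canonical_labels(part$assignment), canonical_labels(oracle))
    # second, library-based oracle route
    if (requireNamespace("igraph", quietly = TRUE)) {
      d <- as.matrix(dist(cbind(tab$x, tab$y)))
      g <- igraph::graph_from_adjacency_matrix(d < t_nm, mode = "undirected",
                                               diag = FALSE)
      expect_equal(canonical_labels(part$assignment),
                   canonical_labels(igraph::components(g)$membership))
    }
    # permutation invariance up to relabeling
    perm <- sample.int(nrow(tab))
    shuffled <- localization_table(tab$x[perm], tab$y[perm],
                                   channel_label = "c5")
    part2 <- partition_localizations(shuffled, t_nm)
    expect_equal(canonical_labels(part2$assignment[order(perm)]),
                 canonical_labels(part$assignment))
    # conservation: every record assigned, ids contiguous
    expect_equal(sort(unique(part$assignment)), seq_len(part$n_clusters))
  }
})

test_that("cluster properties: analytic fixtures and hull oracle", {
  tri <- localization_table(c(0, 100, 0), c(0, 0, 100), channel_label = "c5")
  props <- compute_cluster_properties(tri, partition_localizations(tri, 200))
  expect_equal(props$n_points, 3L)
  expect_equal(props$area_um2, 0.005)
  expect_equal(props$density_per_um2, 600)
  expect_false(props$degenerate)
  # hull is counter-clockwise and contains all members
  expect_gt(sum(props$hull[[1]][c(3, 1, 2), 1] * props$hull[[1]][, 2] -
                  props$hull[[1]][, 1] * props$hull[[1]][c(3, 1, 2), 2]) / 2, 0)

  coll <- localization_table(c(0, 50, 100), c(0, 50, 100), channel_label = "c5")
  pc <- compute_cluster_properties(coll, partition_localizations(coll, 200))
  expect_true(pc$degenerate)
  expect_equal(pc$area_um2, 0)
  expect_true(is.na(pc$density_per_um2))
  expect_equal(cluster_summary(pc)$n_density, 0L)

  set.seed(9)
  for (rep in 1:10) {
    r <- sqrt(runif(30)) * 500
    a <- runif(30, 0, 2 * pi)
    disc <- localization_table(r * cos(a), r * sin(a), channel_label = "c5")
    pd <- compute_cluster_properties(disc, partition_localizations(disc, 1e5))
    expect_equal(pd$area_um2 * 1e6, oracle_hull_area(disc$x, disc$y),
                 tolerance = 1e-9)
    expect_equal(pd$density_per_um2 * pd$area_um2, pd$n_points,
                 tolerance = 1e-6)
    # hull contains all members
    expect_true(all(points_in_polygon(disc$x, disc$y,
                                      pd$hull[[1]][, 1], pd$hull[[1]][, 2],
                                      boundary_eps = 1e-3)))
  }

  short <- localization_table(c(0, 10), c(0, 10), channel_label = "c5")
  expect_error(
    compute_cluster_properties(tri, partition_localizations(short, 70)),
    class = "tjstorm_consistency_error")
})

test_that("rigid motions leave partitions, areas and densities unchanged", {
  set.seed(3)
  tab <- random_table(150)
  part <- partition_localizations(tab, 70)
  props <- compute_cluster_properties(tab, part)
  th <- 0.7
  rx <- tab$x * cos(th) - tab$y * sin(th) + 1234.5
  ry <- tab$x * sin(th) + tab$y * cos(th) - 987.6
  rtab <- localization_table(rx, ry, channel_label = "c5")
  rpart <- partition_localizations(rtab, 70)
  expect_equal(canonical_labels(rpart$assignment),
               canonical_labels(part$assignment))
  rprops <- compute_cluster_properties(rtab, rpart)
  o <- order(props$n_points, props$area_um2)
  ro <- order(rprops$n_points, rprops$area_um2)
  expect_equal(rprops$area_um2[ro], props$area_um2[o], tolerance = 1e-9)
  expect_equal(rprops$density_per_um2[ro], props$density_per_um2[o],
               tolerance = 1e-9)
})

test_that("threshold sweep: refinement, stability, empty input", {
  expect_error(threshold_sweep(random_table(10), c(70, 50)),
               class = "tjstorm_parameter_error")

  set.seed(17)
  tab <- random_table(200)
  sw <- threshold_sweep(tab, c(50, 70, 100))
  # refinement: every 50 nm cluster maps into exactly one 100 nm cluster
  a50 <- sw$partitions[[1]]$assignment
  a100 <- sw$partitions[[3]]$assignment
  expect_true(all(tapply(a100, a50, function(v) length(unique(v))) == 1L))

  # one tight isolated cluster: count 1 at every threshold in 50-100
  set.seed(21)
  iso <- localization_table(rnorm(80, 0, 10), rnorm(80, 0, 10),
                            channel_label = "c5")
  swi <- threshold_sweep(iso, c(50, 60, 70, 80, 90, 100))
  expect_true(all(swi$summary$n_clusters == 1L))

  empty <- localization_table(numeric(0), numeric(0), channel_label = "c5")
  swe <- threshold_sweep(empty, c(50, 100))
  expect_true(all(swe$summary$n_clusters == 0L))
})

test_that("cluster summary arithmetic and planted-density recovery", {
  fake <- data.frame(cluster_id = 1:2, n_points = c(10L, 30L),
                     area_um2 = c(0.1, 0.1),
                     density_per_um2 = c(100, 300),
                     centroid_x_nm = 0, centroid_y_nm = 0,
                     degenerate = FALSE)
  class(fake) <- c("cluster_properties", "data.frame")
  s <- cluster_summary(fake)
  expect_equal(s$mean_density, 200)
  expect_equal(s$n_clusters, 2L)
  expect_equal(sum(s$area_hist$count), 2L)

  se <- cluster_summary(fake[0, ])
  expect_equal(se$n_clusters, 0L)
  expect_true(all(se$area_hist$count == 0L))

  # planted density is recovered by the summary on a well-separated scene
  sc <- generate_scene(scene_config(geometry = "ring", n_clusters = 20,
                                    ring_diameter_um = 11.1,
                                    cluster_spacing = "even",
                                    cluster_shape = "disc",
                                    cluster_radius_nm = 100,
                                    molecules_per_cluster = 120,
                                    background_rate_um2 = 0, seed = 202))
  part <- partition_localizations(sc$channels$claudin5, 70)
  props <- compute_cluster_properties(sc$channels$claudin5, part)
  s2 <- cluster_summary(props)
  planted <- sc$truth$clusters$planted_density_per_um2
  expect_equal(s2$n_clusters, 20L)
  expect_lt(abs(s2$mean_density - mean(planted)), 3 * s2$se_density + 1e-9)
})
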