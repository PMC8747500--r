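test_that("scene generation is deterministic and seed-scoped", {
  cfg <- scene_preset("P9", seed = 99,
                      tracer = list(luminal_density_um2 = 100,
                                    abluminal_density_um2 = 10))
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$truth$clusters, s2$truth$clusters)

  s3 <- generate_scene(scene_preset("P9", seed = 100,
                                    tracer = cfg$tracer))
  expect_false(identical(s1$channels$claudin5$x, s3$channels$claudin5$x))

  # caller RNG state is untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_scene(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("configuration validation", {
  expect_error(scene_config(sigma_loc_nm = 0), class = "tjstorm_config_error")
  expect_error(scene_config(geometry = "dispersed",
                            tracer = list(luminal_density_um2 = 1)),
               class = "tjstorm_config_error")
  expect_error(scene_config(background_rate_um2 = -1),
               class = "tjstorm_config_error")
})

test_that("localization counts match the compound-process closed form", {
  lambda <- 30; b <- 3; n_c <- 10L; bg_rate <- 5
  cfgs <- lapply(1:100, function(s)
    scene_config(geometry = "ring", n_clusters = n_c,
                 molecules_per_cluster = lambda, blinks_per_molecule = b,
                 cluster_radius_nm = 50, cluster_shape = "disc",
                 background_rate_um2 = bg_rate, seed = 3000 + s))
  totals <- vapply(cfgs, function(cf) nrow(generate_scene(cf)$channels$claudin5),
                   numeric(1))
  # zero-truncated Poisson moments
  em <- lambda / (1 - exp(-lambda))
  vm <- (lambda + lambda^2) / (1 - exp(-lambda)) - em^2
  # geometric (support >= 1) blink moments
  eb <- b; vb <- b * (b - 1)
  e_s <- em * eb
  v_s <- em * vb + vm * eb^2
  side_um <- generate_scene(cfgs[[1]])$truth$field_side_nm / 1e3
  e_bg <- bg_rate * side_um^2
  e_total <- n_c * e_s + e_bg
  v_total <- n_c * v_s + e_bg
  expect_lt(abs(mean(totals) - e_total), 3 * sqrt(v_total / 100))
})

test_that("degenerate limit: one blink, vanishing noise", {
  cfg <- scene_config(n_clusters = 5L, molecules_per_cluster = 20,
                      blinks_per_molecule = 1, sigma_loc_nm = 1e-9,
                      cluster_radius_nm = 100, seed = 8)
  sc <- generate_scene(cfg)
  lin <- sc$truth$lineage
  mols <- sc$truth$molecules
  expect_equal(nrow(sc$channels$claudin5), nrow(mols))
  idx <- match(lin$molecule_id, mols$molecule_id)
  expect_lt(max(abs(sc$channels$claudin5$x - mols$x[idx])), 1e-6)
  expect_lt(max(abs(sc$channels$claudin5$y - mols$y[idx])), 1e-6)
})

test_that("count conservation across lineage, background and tracer", {
  cfg <- scene_preset("P9", seed = 17,
                      tracer = list(luminal_density_um2 = 150,
                                    abluminal_density_um2 = 20))
  sc <- generate_scene(cfg)
  lin <- sc$truth$lineage
  expect_equal(nrow(sc$channels$claudin5), nrow(lin))
  expect_equal(sum(lin$source == "cluster"),
               sum(sc$truth$molecules$n_blinks))
  expect_equal(sum(sc$truth$clusters$n_localizations),
               sum(lin$source == "cluster"))
  expect_equal(nrow(sc$channels$tracer), nrow(sc$truth$tracer))
  # every localization traces to exactly one origin
  expect_true(all(lin$source %in% c("cluster", "background")))
  expect_true(all(!is.na(lin$molecule_id[lin$source == "cluster"])))
})

test_that("planted recovery: single cluster, blink doubling", {
  one <- generate_scene(scene_config(n_clusters = 1L, cluster_radius_nm = 50,
                                     cluster_shape = "disc",
                                     background_rate_um2 = 0, seed = 12))
  part <- partition_localizations(one$channels$claudin5, 70)
  rep1 <- planted_recovery_report(one, part)
  expect_equal(rep1$recovered_n_clusters, 1L)
  expect_equal(rep1$ari, 1)

  expect_error(
    planted_recovery_report(one, partition_localizations(
      localization_table(1:5, 1:5, channel_label = "claudin5"), 70)),
    class = "tjstorm_consistency_error")

  # overcounting is multiplicative: doubling mean blinks doubles mean
  # localizations per cluster
  mean_pts <- function(b, seeds) {
    vapply(seeds, function(s) {
      sc <- generate_scene(scene_config(n_clusters = 6L,
                                        molecules_per_cluster = 25,
                                        blinks_per_molecule = b,
                                        cluster_radius_nm = 50,
                                        cluster_shape = "disc",
                                        background_rate_um2 = 0,
                                        seed = s))
      mean(sc$truth$clusters$n_localizations)
    }, numeric(1))
  }
  m2 <- mean_pts(2, 1:100)
  m4 <- mean_pts(4, 201:300)
  se <- sqrt(stats::var(m4) / 100 + 4 * stats::var(m2) / 100)
  expect_lt(abs(mean(m4) - 2 * mean(m2)), 3 * se)
})

test_that("scene export writes channels, ROI, truth and config", {
  d <- withr::local_tempdir()
  sc <- generate_scene(scene_preset("P9", seed = 2,
                                    tracer = list(luminal_density_um2 = 50,
                                                  abluminal_density_um2 = 5)))
  write_scene(sc, d)
  expect_true(file.exists(file.path(d, "claudin5.csv")))
  expect_true(file.exists(file.path(d, "tracer.csv")))
  expect_true(file.exists(file.path(d, "ring.json")))
  back <- read_molecular_list(file.path(d, "claudin5.csv"),
                              channel_label = "claudin5")
  expect_equal(back$x, sc$channels$claudin5$x, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$config$seed, 2L)
  expect_equal(nrow(truth$clusters), nrow(sc$truth$clusters))
  ring <- read_roi(file.path(d, "ring.json"))
  expect_equal(estimate_diameter(ring), 5.9, tolerance = 0.01)
})
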