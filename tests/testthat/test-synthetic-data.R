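test_that("coordinates are mirrored, boxed and reproducible", {
  two <- generate_coordinates(2, seed = 1)
  expect_equal(two$x[1], -two$x[2])
  expect_equal(two$y[1], two$y[2])
  expect_equal(two$z[1], two$z[2])

  co <- generate_coordinates(90, seed = 7)
  d <- as.matrix(dist(coord <- as.matrix(co[, c("x", "y", "z")])))
  dv <- d[upper.tri(d)]
  expect_true(all(dv > 0))
  expect_true(all(dv <= sqrt(140^2 + 170^2 + 120^2)))
  expect_true(all(abs(co$x) <= 70 & abs(co$y) <= 85 & abs(co$z) <= 60))

  expect_identical(co, generate_coordinates(90, seed = 7))
  expect_error(generate_coordinates(1, seed = 1), "n_regions")
})

test_that("spatial modular networks have the exact edge count and are simple", {
  co <- generate_coordinates(10, seed = 3)
  cfg <- synthetic_config(n_regions = 10, n_modules = 2, sparsity = 0.2,
                          seed = 3)
  truth <- generate_spatial_modular_network(co, cfg)
  expect_equal(edge_count(truth$network), 9)   # 0.2 * 45

  for (sd in 1:5) {
    cfg <- synthetic_config(n_regions = 30, n_modules = 3, sparsity = 0.15,
                            seed = sd)
    a <- generate_spatial_modular_network(
      generate_coordinates(30, seed = sd), cfg)$network$adjacency
    expect_identical(a, t(a))
    expect_true(all(diag(a) == 0))
    expect_true(all(a %in% c(0L, 1L)))
    expect_equal(sum(a) / 2, floor(0.15 * 435 + 0.5))
  }
})

test_that("module boost concentrates edges within modules", {
  frac_within <- function(boost, sd) {
    co <- generate_coordinates(90, seed = sd)
    cfg <- synthetic_config(within_module_boost = boost,
                            distance_decay_lambda = 20, seed = sd)
    truth <- generate_spatial_modular_network(co, cfg)
    a <- truth$network$adjacency
    same <- outer(truth$module_assignment, truth$module_assignment, "==")
    sum(a[same]) / sum(a)
  }
  boosted <- vapply(1:20, function(sd) frac_within(50, sd), numeric(1))
  flat <- vapply(1:20, function(sd) frac_within(1, sd), numeric(1))
  expect_gt(mean(boosted), mean(flat))
  expect_true(all(boosted > flat))
})

test_that("infinite decay and no boost reduce to a uniform random graph", {
  co <- generate_coordinates(20, seed = 5)
  cfg <- synthetic_config(n_regions = 20, n_modules = 2, sparsity = 0.2,
                          distance_decay_lambda = Inf,
                          within_module_boost = 1, seed = 5)
  truth <- generate_spatial_modular_network(co, cfg)
  expect_equal(edge_count(truth$network), floor(0.2 * 190 + 0.5))
})

test_that("time series covariance reflects the planted edges", {
  co <- generate_coordinates(40, seed = 2)
  # no coupling: off-diagonal correlations are null
  cfg0 <- synthetic_config(n_regions = 40, coupling_strength = 0, seed = 2)
  mean_abs_r <- vapply(1:5, function(sd) {
    cfg0$seed <- sd
    truth <- generate_spatial_modular_network(co, cfg0)
    cfg0$seed <- sd + 100
    r <- pearson_correlation_matrix(generate_time_series(truth, cfg0))
    mean(abs(r[upper.tri(r)]))
  }, numeric(1))
  expect_lt(mean(mean_abs_r), 0.1)

  # strong coupling: edge pairs out-correlate non-edge pairs, every seed
  cfg1 <- synthetic_config(n_regions = 40, coupling_strength = 0.8, seed = 2)
  diffs <- vapply(1:20, function(sd) {
    cfg1$seed <- sd
    truth <- generate_spatial_modular_network(co, cfg1)
    cfg1$seed <- sd + 100
    r <- suppressMessages(
      pearson_correlation_matrix(generate_time_series(truth, cfg1)))
    a <- truth$network$adjacency
    up <- upper.tri(r)
    mean(r[up & a == 1]) - mean(r[up & a == 0])
  }, numeric(1))
  expect_true(all(diffs > 0))

  # determinism
  cfg1$seed <- 9
  truth <- generate_spatial_modular_network(co, cfg1)
  expect_identical(suppressMessages(generate_time_series(truth, cfg1)),
                   suppressMessages(generate_time_series(truth, cfg1)))
})

test_that("thresholding recovers planted edges far above chance", {
  hits <- vapply(1:20, function(sd) {
    cfg <- synthetic_config(n_regions = 40, coupling_strength = 0.5,
                            seed = sd)
    co <- generate_coordinates(40, seed = sd)
    truth <- generate_spatial_modular_network(co, cfg)
    cfg$seed <- sd + 1
    ts <- suppressMessages(generate_time_series(truth, cfg))
    net <- threshold_by_sparsity(pearson_correlation_matrix(ts),
                                 cfg$sparsity)
    sum(net$adjacency * truth$network$adjacency) /
      sum(truth$network$adjacency)
  }, numeric(1))
  expect_true(all(hits > 3 * 0.15))   # chance level is the sparsity itself
})

test_that("small-world scalar is ~1 on random graphs and reproducible", {
  net <- rand_connected_network(60, 300, seed = 4)
  sig <- small_world_scalar(net, n_random = 20, seed = 1)
  expect_gt(sig, 0.7)
  expect_lt(sig, 1.4)
  expect_identical(small_world_scalar(net, n_random = 5, seed = 2),
                   small_world_scalar(net, n_random = 5, seed = 2))
  empty <- brain_network(matrix(0L, 3, 3))
  expect_error(small_world_scalar(empty), "no edges")
})

test_that("synthetic subject files round-trip through TSV", {
  co <- generate_coordinates(12, seed = 8)
  cfg <- synthetic_config(n_regions = 12, n_modules = 2, sparsity = 0.3,
                          seed = 8)
  truth <- generate_spatial_modular_network(co, cfg)
  ts <- suppressMessages(generate_time_series(truth, cfg))
  dir <- withr::local_tempdir()
  write_synthetic_subject(truth, ts, dir)
  expect_equal(read_coordinates(file.path(dir, "coordinates.tsv")), co,
               tolerance = 1e-12)
  ts2 <- read_timeseries(file.path(dir, "timeseries.tsv"))
  expect_equal(ts2, ts, tolerance = 1e-12)
  net2 <- read_edge_list(file.path(dir, "truth_edges.tsv"),
                         labels = truth$network$labels)
  expect_identical(net2$adjacency, truth$network$adjacency)
})
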