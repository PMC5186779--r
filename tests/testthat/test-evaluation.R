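test_that("relative errors follow the percent definition", {
  expect_equal(relative_error(0.5, 0.45), 10)
  expect_equal(relative_error(0.4, 0.4), 0)
  expect_warning(re0 <- relative_error(0, 3), "zero reference")
  expect_true(is.na(re0))
})

test_that("degree-distribution error averages the two parameter errors", {
  f <- function(a, k) structure(list(alpha = a, k_c = k, fit_error = 0),
                                class = "degree_fit")
  expect_equal(degree_distribution_error(f(2, 10), f(1.5, 12)),
               (25 + 20) / 2)
  expect_equal(degree_distribution_error(f(1.7, 14), f(1.7, 14)), 0)
  expect_true(is.na(degree_distribution_error(NULL, f(1, 1))))
})

test_that("energy is the reciprocal summed error with a perfect-cap", {
  expect_equal(energy(rep(0.125, 8)), 1)
  expect_equal(energy(rep(0.0625, 8)), 2)
  set.seed(71)
  re <- runif(8, 0.01, 0.5)
  expect_equal(energy(re), 1 / sum(re), tolerance = 1e-12)
  expect_warning(e <- energy(rep(0, 8)), "perfect")
  expect_equal(e, 1e6)
  expect_true(is.na(energy(c(rep(0.1, 7), NA))))
  expect_error(energy(rep(0.1, 5)), "eight")
})

test_that("prediction power measures edge recovery against chance", {
  real <- rand_network(30, 60, seed = 21)
  # chance-level by construction: overlap such that Pre_M = Pre_R
  # (take a prediction equal to real: Pre_M = 1)
  expect_equal(prediction_power(real, real), 10 * log10(435 / 60))

  # hand-computed from a known overlap
  pred <- rand_network(30, 60, seed = 22)
  ov <- sum(pred$adjacency * real$adjacency) / 2
  expect_equal(prediction_power(pred, real),
               10 * log10((ov / 60) / (60 / 435)))

  # Monte-Carlo baseline approaches the analytic expectation
  pp_mc <- prediction_power(pred, real, baseline = "monte_carlo",
                            n_random = 2000, seed = 1)
  expect_equal(pp_mc, prediction_power(pred, real), tolerance = 0.2)

  mism <- rand_network(30, 61, seed = 23)
  expect_error(prediction_power(mism, real), "edge counts differ")

  # zero overlap floors at half an edge with a warning
  a <- matrix(0L, 30, 30); a[1, 2] <- a[2, 1] <- 1L
  b <- matrix(0L, 30, 30); b[3, 4] <- b[4, 3] <- 1L
  expect_warning(pp0 <- prediction_power(brain_network(a),
                                         brain_network(b)), "floor")
  expect_equal(pp0, 10 * log10((0.5) / (1 / 435)))
})

test_that("the paired signed-rank test uses the exact distribution", {
  expect_equal(paired_property_test(1:6, 1:6), 1)
  expect_equal(paired_property_test(2:7 + 0.1 * (1:6), 1:6), 2 / 64)
  expect_error(paired_property_test(1:5, 1:5), "at least 6")
  expect_error(paired_property_test(1:6, 1:5), "equal length")
})

test_that("BH step-up rejections match the hand-run procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.05, 0.20)),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(bh_fdr(rep(0.001, 7))))
  expect_false(any(bh_fdr(rep(0.9, 5))))
  expect_identical(bh_fdr(numeric(0)), logical(0))
  # monotone: rejecting p_j implies rejecting any smaller p_i
  set.seed(81)
  for (rep_i in 1:20) {
    p <- runif(10)
    flags <- bh_fdr(p)
    if (any(flags)) expect_true(all(flags[p <= max(p[flags])]))
  }
})

test_that("one-way ANOVA matches the hand-computed F", {
  # hand computation: group means 2 and 5, grand mean 3.5, so
  # SSB = 3*(1.5^2)*2 = 13.5 on 1 df; SSW = 2+2 = 4 on 4 df; F = 13.5
  out <- model_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out$F, 13.5)
  expect_equal(out$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(model_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  expect_error(model_anova(list(1:3)), "2 groups")
})

test_that("energy-power correlation matches the direct formula", {
  e <- c(1, 2, 3, 4, 5)
  expect_equal(energy_power_correlation(e, 2 * e + 1)$r, 1)
  expect_equal(energy_power_correlation(e, -e)$r, -1)
  set.seed(91)
  x <- rnorm(28); y <- rnorm(28)
  out <- energy_power_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_direct, tolerance = 1e-10)
  expect_error(energy_power_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("evaluate_models on a self-predicting subject is perfect", {
  grid <- sparsity_grid()
  set.seed(101)
  real <- list(lapply(seq_along(grid), function(i) {
    rand_network(30, floor(grid[i] * 435 + 0.5), seed = 600 + i)
  }))
  preds <- list(lapply(stats::setNames(similarity_indices(),
                                       similarity_indices()),
                       function(idx) list(networks = real[[1]], gamma = 0)))
  rep <- suppressWarnings(evaluate_models(real, preds))
  expect_true(all(rep$property_errors$re_percent == 0, na.rm = TRUE))
  expect_true(all(rep$per_subject$energy == 1e6))
  bound_pp <- mean(10 * log10(435 / floor(grid * 435 + 0.5)))
  expect_equal(unique(round(rep$per_subject$prediction_power, 10)),
               round(bound_pp, 10))
  # group statistics need more subjects and must be NA, not wrong
  expect_true(all(is.na(rep$group_tests$p)))
})

test_that("evaluation reports are schema-complete and reproducible", {
  cfg <- synthetic_config(n_regions = 40, seed = 1)
  rep1 <- suppressMessages(run_study(n_subjects = 3, config = cfg,
                                     indices = c("CN", "PA"), seed = 5))
  rep2 <- suppressMessages(run_study(n_subjects = 3, config = cfg,
                                     indices = c("CN", "PA"), seed = 5))
  expect_identical(report_to_json(rep1), report_to_json(rep2))
  expect_setequal(names(rep1),
                  c("per_subject", "property_errors", "pp_by_sparsity",
                    "group_tests", "anova", "correlations", "settings"))
  expect_equal(nrow(rep1$per_subject), 3 * 2)
  expect_equal(nrow(rep1$property_errors), 3 * 2 * 8)
  expect_setequal(unique(rep1$property_errors$property),
                  c("R", "C", "L", "Eglob", "Eloc", "Q", "T", "Pk"))
  expect_true(all(is.finite(rep1$per_subject$prediction_power)))
})
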