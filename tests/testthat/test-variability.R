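test_that("bootstrap fold quantile handles the degenerate and exact cases", {
  s <- bootstrap_settings(n_boot = 500, subgroup_sizes = c(3, 3), seed = 1)
  expect_identical(bootstrap_fold_quantile(rep(5, 7), s), 1)

  expect_error(bootstrap_fold_quantile(5, s), "at least 2")
  expect_error(bootstrap_fold_quantile(c(1, -2, 3), s), "positive")
  expect_error(bootstrap_settings(quantile = 1), "between 0 and 1")
  expect_error(bootstrap_settings(subgroup_sizes = c(1, 7)), ">= 2")
})

test_that("bootstrap quantile matches the exhaustively enumerated distribution", {
  s <- bootstrap_settings(n_boot = 1e5, subgroup_sizes = c(2, 2),
                          quantile = 0.95, seed = 31)
  for (v in list(c(1, 1, 1, 1000), c(1.2, 3.4, 2.2, 9.5, 5.1))) {
    exact <- enum_fold_quantile(v, c(2, 2), 0.95)
    boot <- bootstrap_fold_quantile(v, s)
    expect_lt(abs(boot - exact) / exact, 0.01)
  }
})

test_that("bootstrap distribution agrees with an independent sampler (KS oracle)", {
  set.seed(99)
  v <- exp(stats::rnorm(7, 10, 0.3))
  # package path
  s <- bootstrap_settings(n_boot = 1e5, subgroup_sizes = c(7, 7), seed = 41)
  set.seed(12345) # oracle uses its own RNG stream
  oracle <- replicate(2e4, {
    m1 <- mean(sample(v, 7, replace = TRUE))
    m2 <- mean(sample(v, 7, replace = TRUE))
    max(m1, m2) / min(m1, m2)
  })
  # compare the package's bootstrap sample against the oracle's
  n1 <- s$subgroup_sizes[1]
  set.seed(geldd:::substream_seed(s$seed, 0L))
  idx <- sample.int(length(v), 14 * s$n_boot, replace = TRUE)
  m <- matrix(v[idx], nrow = 14)
  pkg_folds <- {
    a <- colMeans(m[1:7, , drop = FALSE]); b <- colMeans(m[8:14, , drop = FALSE])
    pmax(a, b) / pmin(a, b)
  }
  ks <- suppressWarnings(stats::ks.test(pkg_folds, oracle))
  expect_gt(ks$p.value, 0.01)
  # and the quantile the package reports is the quantile of that sample
  expect_equal(bootstrap_fold_quantile(v, s),
               unname(stats::quantile(pkg_folds, 0.95, type = 7)))
})

test_that("the fold quantile is scale-free and monotone in the quantile level", {
  v <- c(3.2, 4.8, 2.9, 7.7, 4.1, 5.0, 3.6)
  s95 <- bootstrap_settings(n_boot = 2000, subgroup_sizes = c(7, 7),
                            quantile = 0.95, seed = 8)
  s99 <- bootstrap_settings(n_boot = 2000, subgroup_sizes = c(7, 7),
                            quantile = 0.99, seed = 8)
  q <- bootstrap_fold_quantile(v, s95)
  expect_gte(q, 1)
  expect_equal(bootstrap_fold_quantile(1e6 * v, s95), q, tolerance = 1e-12)
  expect_gte(bootstrap_fold_quantile(v, s99), q)
})

test_that("estimate_variability excludes zero-volume spots with a warning", {
  vols <- two_group_matrix(
    matrix(c(4, 5, 6, 5, 0, 6, 7, 8, 9), 3, byrow = TRUE),
    matrix(7, 3, 3))
  t0 <- make_table(vols, normalized = TRUE)
  expect_warning(out <- estimate_variability(
    t0, bootstrap_settings(n_boot = 100, subgroup_sizes = c(3, 3))),
    "spot_0002")
  expect_identical(out$spot_id, c("spot_0001", "spot_0003"))
  expect_true(all(out$q95 >= 1))
})

test_that("the threshold GLM recovers a noise-free surface exactly", {
  set.seed(12)
  n <- 60
  spots <- data.frame(spot_id = as.character(1:n),
                      log_mean_volume = stats::runif(n, 8, 16),
                      x = stats::runif(n), y = stats::runif(n))
  spots$q95 <- exp(2 - 0.1 * spots$log_mean_volume)
  prof <- fit_threshold_glm(spots)
  expect_equal(unname(prof$coefficients),
               c(2, -0.1, 0, 0), tolerance = 1e-6)
  expect_equal(prof$data$predicted_threshold, spots$q95, tolerance = 1e-9)

  # constant response: intercept log(c), zero slopes, thresholds = c
  spots$q95 <- 1.4
  prof_c <- fit_threshold_glm(spots)
  expect_equal(unname(prof_c$coefficients), c(log(1.4), 0, 0, 0),
               tolerance = 1e-9)
  expect_equal(prof_c$data$predicted_threshold, rep(1.4, n),
               tolerance = 1e-9)
})

test_that("the threshold GLM recovers noisy coefficients within 3 SE (OLS oracle)", {
  set.seed(77)
  n <- 800
  truth <- c(1.8, -0.09, 0.25, -0.15)
  spots <- data.frame(spot_id = as.character(1:n),
                      log_mean_volume = stats::runif(n, 8, 16),
                      x = stats::runif(n), y = stats::runif(n))
  spots$q95 <- exp(truth[1] + truth[2] * spots$log_mean_volume +
                     truth[3] * spots$x + truth[4] * spots$y +
                     stats::rnorm(n, 0, 0.05))
  prof <- fit_threshold_glm(spots)
  # independent oracle: ordinary least squares by the normal equations
  X <- cbind(1, spots$log_mean_volume, spots$x, spots$y)
  beta <- solve(crossprod(X), crossprod(X, log(spots$q95)))
  expect_equal(unname(prof$coefficients), drop(beta), tolerance = 1e-8)
  resid <- log(spots$q95) - X %*% beta
  se <- sqrt(diag(solve(crossprod(X))) *
               sum(resid^2) / (n - 4))
  expect_true(all(abs(unname(prof$coefficients) - truth) < 3 * se))
})

test_that("degenerate designs are rejected with a fallback hint", {
  spots <- data.frame(spot_id = as.character(1:20),
                      q95 = seq(1.1, 1.5, length.out = 20),
                      log_mean_volume = 10, x = stats::runif(20),
                      y = stats::runif(20))
  expect_error(fit_threshold_glm(spots), "intercept_only")
  prof <- fit_threshold_glm(spots, intercept_only = TRUE)
  expect_equal(unname(prof$coefficients[-1]), c(0, 0, 0))
  expect_error(fit_threshold_glm(spots[1:5, ]), "at least 10")
  spots$q95[1] <- 0.9
  expect_error(fit_threshold_glm(spots, intercept_only = TRUE), ">= 1")
})

test_that("threshold prediction is the exponentiated linear predictor, floored at 1", {
  set.seed(5)
  n <- 50
  spots <- data.frame(spot_id = as.character(1:n),
                      log_mean_volume = stats::runif(n, 8, 16),
                      x = stats::runif(n), y = stats::runif(n))
  spots$q95 <- exp(1.2 - 0.06 * spots$log_mean_volume + 0.1 * spots$x +
                     stats::rnorm(n, 0, 0.03))
  prof <- fit_threshold_glm(spots)
  # refit oracle: thresholds on the training spots equal exp(fitted)
  expect_equal(unname(predict_thresholds(prof, spots)),
               prof$data$predicted_threshold, tolerance = 1e-12)

  # intercept-only profile predicts a constant
  spots2 <- spots; spots2$q95 <- 1.5
  prof2 <- fit_threshold_glm(spots2, intercept_only = TRUE)
  expect_equal(unname(predict_thresholds(prof2, spots)), rep(1.5, n),
               tolerance = 1e-9)

  # negative volume slope: thresholds strictly decreasing in volume
  grid <- data.frame(log_mean_volume = seq(8, 16, length.out = 9),
                     x = 0.5, y = 0.5)
  thr <- predict_thresholds(prof, grid)
  expect_true(all(diff(thr) < 0))
})

test_that("predicted thresholds inherit the generator's mean-variance sign", {
  sim <- generate_spot_table(simulation_config(n_spots = 400, seed = 21))
  norm <- normalize_total_volume(sim$table)$table
  prof <- fit_threshold_glm(estimate_variability(
    norm, bootstrap_settings(n_boot = 300, seed = 7)))
  rho <- stats::cor(prof$data$predicted_threshold,
                    prof$data$log_mean_volume, method = "spearman")
  expect_lt(rho, 0) # cv_slope_logvolume < 0 by default
})

test_that("variability profiles round-trip through CSV + JSON sidecar", {
  sim <- generate_spot_table(simulation_config(n_spots = 50, seed = 2))
  prof <- fit_threshold_glm(estimate_variability(
    normalize_total_volume(sim$table)$table,
    bootstrap_settings(n_boot = 200, seed = 3)))
  path <- tempfile(fileext = ".csv")
  write_variability_profile(prof, path)
  back <- read_variability_profile(path)
  expect_equal(back$coefficients, prof$coefficients, tolerance = 1e-12)
  expect_equal(back$data$predicted_threshold,
               prof$data$predicted_threshold, tolerance = 1e-12)
})
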