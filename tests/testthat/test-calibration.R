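test_that("gaussian kernel weight has its analytic values and decays", {
  expect_identical(gaussian_weight(0, 1000), 1)
  expect_equal(gaussian_weight(1000, 1000), exp(-1))
  expect_equal(gaussian_weight(2000, 1000), exp(-4))
  d <- seq(0, 10000, by = 100)
  w <- gaussian_weight(d, 3000)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(gaussian_weight(100, 0), class = "value_error")
  expect_error(gaussian_weight(100, -5), class = "value_error")
  expect_error(gaussian_weight(-1, 100), class = "value_error")
})

test_that("global fit recovers an exact line", {
  x <- c(10, 20, 30, 50, 80)
  pairs <- make_pairs(y = 2 * x + 1, x1 = x, u = seq_along(x), v = seq_along(x))
  fit <- fit_global(pairs)
  expect_equal(unname(fit$beta), c(1, 2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  expect_equal(tidy(fit)$estimate, c(1, 2), tolerance = 1e-12)
})

test_that("a constant covariate makes the global fit singular", {
  pairs <- make_pairs(y = c(10, 20, 30, 40), x1 = rep(25, 4), u = 1:4, v = 1:4)
  expect_error(fit_global(pairs), class = "singular_fit_error")
})

test_that("global fit matches the normal-equations oracle on noisy data", {
  withr::with_seed(12, {
    x <- runif(20, 10, 100)
    y <- 3 + 0.8 * x + rnorm(20, 0, 4)
  })
  pairs <- make_pairs(y = y, x1 = x, u = runif(20), v = runif(20))
  fit <- fit_global(pairs)
  expect_equal(unname(fit$beta), unname(oracle_ols(cbind(1, x), y)),
               tolerance = 1e-10)
})

test_that("local and global fits agree with independent WLS/OLS oracles", {
  for (seed in 1:60) {
    pairs <- random_instance(seed)
    B <- attr(pairs, "B")
    X <- cbind(1, as.matrix(tibble::as_tibble(pairs)[, paste0("x", 1:B)]))
    target <- c(mean(pairs$u), mean(pairs$v))
    b <- 5e4
    w <- exp(-((pairs$u - target[1])^2 + (pairs$v - target[2])^2) / b^2)
    beta <- fit_local(pairs, target[1], target[2], b)
    expect_equal(as.numeric(beta), unname(oracle_wls(X, w, pairs$y)),
                 tolerance = 1e-8)
    expect_equal(unname(fit_global(pairs)$beta),
                 unname(oracle_ols(X, pairs$y)), tolerance = 1e-8)
  }
})

test_that("in the large-bandwidth limit every local fit equals the global fit", {
  pairs <- random_instance(99, n = 40, B = 1)
  diam <- max(dist(cbind(pairs$u, pairs$v)))
  fit_g <- fit_global(pairs)
  sp <- fit_spatial(pairs, bandwidth = 1e4 * diam)
  for (i in seq_len(nrow(pairs))) {
    expect_equal(unname(as.numeric(sp$local_coefficients[i, c("(Intercept)", "x1")])),
                 unname(fit_g$beta), tolerance = 1e-6)
  }
})

test_that("too few pairs within reach raises an underdetermined error", {
  pairs <- make_pairs(y = c(10, 20, 30), x1 = c(5, 15, 25),
                      u = c(0, 1e6, 2e6), v = c(0, 0, 0))
  expect_error(fit_local(pairs, 0, 0, bandwidth = 1000),
               class = "underdetermined_local_fit_error")
})

test_that("locally constant covariate triggers ridge handling", {
  pairs <- make_pairs(y = c(10, 12, 14, 16), x1 = rep(30, 4),
                      u = c(0, 100, 200, 300), v = rep(0, 4))
  beta <- suppressMessages(fit_local(pairs, 0, 0, bandwidth = 1e4))
  expect_true(attr(beta, "ridge"))
  expect_true(all(is.finite(beta)))
  # the regularized slope collapses toward zero
  expect_lt(abs(beta[["x1"]]), 1e-3)
})

test_that("spatial fit stores one finite coefficient vector per anchor", {
  fx <- fixture_76_stations()
  pairs <- suppressMessages(
    filter_pairs(collocate_nearest(fx$stations, fx$sensors), 2000))
  sp <- fit_spatial(pairs, bandwidth = 5e4)
  expect_equal(nrow(sp$local_coefficients), 69)
  expect_true(all(is.finite(as.matrix(
    sp$local_coefficients[, c("(Intercept)", "x1")]))))
  expect_equal(nrow(tidy(sp)), 69 * 2)
  expect_equal(glance(sp)$bandwidth, 5e4)
})

test_that("homogeneous data yields local slopes close to the global slope at wide bandwidths", {
  net <- generate_network(default_scenario(seed = 3, bias_form = "constant"))
  pairs <- filter_pairs(collocate_nearest(net$stations, net$sensors), 2000)
  g <- fit_global(pairs)
  # a bandwidth on the order of the domain pools most pairs at every anchor,
  # so the noise-driven wiggle of the local slopes collapses
  sp_wide <- fit_spatial(pairs, bandwidth = 2e5)
  expect_lt(max(abs(sp_wide$local_coefficients$x1 - g$beta[["x1"]])), 0.2)
  sp_narrow <- fit_spatial(pairs, bandwidth = 5e4)
  expect_lt(max(abs(sp_wide$local_coefficients$x1 - g$beta[["x1"]])),
            max(abs(sp_narrow$local_coefficients$x1 - g$beta[["x1"]])))
})

test_that("coefficient surfaces vary smoothly on heterogeneous data", {
  net <- generate_network(default_scenario(seed = 4))
  pairs <- filter_pairs(collocate_nearest(net$stations, net$sensors), 2000)
  sp <- fit_spatial(pairs, bandwidth = 4e4)
  lc <- sp$local_coefficients
  ii <- t(utils::combn(nrow(lc), 2))
  d_anchor <- sqrt((lc$u[ii[, 1]] - lc$u[ii[, 2]])^2 +
                     (lc$v[ii[, 1]] - lc$v[ii[, 2]])^2)
  d_slope <- abs(lc$x1[ii[, 1]] - lc$x1[ii[, 2]])
  # |slope difference| increases with anchor separation on average
  expect_gt(cor(d_anchor, d_slope, method = "spearman"), 0.2)
})

test_that("bandwidth selection returns the single candidate unchanged", {
  pairs <- random_instance(7, n = 30, B = 1)
  expect_equal(as.numeric(select_bandwidth(pairs, candidates = 5e4)), 5e4)
})

test_that("bandwidth CV matches an independent leave-one-out loop and prefers large bandwidths for constant coefficients", {
  # constant true coefficients: y = 2 + 0.5 x + small noise
  withr::with_seed(21, {
    n <- 40
    u <- runif(n, 0, 2e5); v <- runif(n, 0, 2e5)
    x <- runif(n, 20, 100)
    y <- 2 + 0.5 * x + rnorm(n, 0, 1)
  })
  pairs <- make_pairs(y = y, x1 = x, u = u, v = v)
  cands <- c(2e3, 2e4, 2e5)
  sel <- select_bandwidth(pairs, candidates = cands)
  expect_equal(as.numeric(sel), 2e5)

  # oracle: hand-rolled LOO loop via the WLS oracle
  cv <- attr(sel, "cv")
  X <- cbind(1, x)
  for (k in 2:3) {   # smallest candidate can be degenerate by design
    b <- cands[k]
    err <- sapply(seq_len(n), function(i) {
      w <- exp(-((u - u[i])^2 + (v - v[i])^2) / b^2)[-i]
      bhat <- oracle_wls(X[-i, , drop = FALSE], w, y[-i])
      y[i] - sum(X[i, ] * bhat)
    })
    expect_equal(cv$cv_rmse[k], sqrt(mean(err^2)), tolerance = 1e-8)
  }
})

test_that("strongly varying slope surfaces select a bandwidth below the maximum", {
  d <- generate_vc_data(150, beta1 = c(0.3, 1.2), noise_sd = 0.5, seed = 9)
  sel <- select_bandwidth(d$pairs, candidates = c(2e3, 2e4, 2e5))
  expect_lt(as.numeric(sel), 2e5)
})

test_that("local fits recover a linear slope surface from exact data", {
  d <- generate_vc_data(400, noise_sd = 0, seed = 2)
  b <- as.numeric(select_bandwidth(
    d$pairs, candidates = exp(seq(log(1e4), log(4e5), length.out = 10))))
  sp <- fit_spatial(d$pairs, b)
  rel_rmse <- sqrt(mean((sp$local_coefficients$x1 - d$truth$beta1)^2)) /
    mean(abs(d$truth$beta1))
  expect_lt(rel_rmse, 0.05)
})

test_that("identity coefficients leave readings unchanged and affine ones apply exactly", {
  sensors <- make_obs(paste0("s", 1:4), 1:4, 1:4, c(10, 50, 100, 0))
  ident <- structure(
    list(beta = c("(Intercept)" = 0, x1 = 1), n_train = 10, B = 1L,
         covariates = "pm25", fitted = NULL, r_squared = 1, rmse = 0),
    class = "global_calibration")
  out <- calibrate(ident, sensors)
  expect_equal(out$pm25, sensors$pm25)

  affine <- ident
  affine$beta <- c("(Intercept)" = 2.8, x1 = 0.93)
  out2 <- calibrate(affine, make_obs("s1", 0, 0, 100))
  expect_equal(out2$pm25, 95.8)
})

test_that("negative calibrated values are floored at zero and counted", {
  sensors <- make_obs(paste0("s", 1:3), 1:3, 1:3, c(1, 2, 100))
  neg <- structure(
    list(beta = c("(Intercept)" = -10, x1 = 1), n_train = 10, B = 1L,
         covariates = "pm25", fitted = NULL, r_squared = 1, rmse = 0),
    class = "global_calibration")
  out <- suppressMessages(calibrate(neg, sensors))
  expect_equal(out$pm25, c(0, 0, 90))
  expect_equal(attr(out, "n_floored"), 2)
})

test_that("spatial calibration at a training anchor reproduces the stored coefficients", {
  pairs <- random_instance(42, n = 30, B = 1)
  sp <- fit_spatial(pairs, bandwidth = 3e4)
  i <- 11
  sensors <- make_obs("probe", pairs$u[i], pairs$v[i], 60)
  out <- calibrate(sp, sensors)
  expected <- sp$local_coefficients$`(Intercept)`[i] +
    sp$local_coefficients$x1[i] * 60
  expect_equal(out$pm25, expected, tolerance = 1e-12)
  # nearest-anchor mode agrees at an anchor by construction
  out2 <- calibrate(sp, sensors, method = "nearest_anchor")
  expect_equal(out2$pm25, expected, tolerance = 1e-12)
})

test_that("calibrating without a required covariate is a configuration error", {
  pairs <- random_instance(13, n = 25, B = 2)
  g <- fit_global(pairs)
  sensors <- make_obs("s1", 0, 0, 50)   # lacks the second covariate
  expect_error(calibrate(g, sensors), class = "configuration_error")
})

test_that("models round-trip through JSON serialization", {
  pairs <- random_instance(55, n = 30, B = 1)
  g <- fit_global(pairs)
  sp <- fit_spatial(pairs, bandwidth = 4e4)
  pg <- withr::local_tempfile(fileext = ".json")
  ps <- withr::local_tempfile(fileext = ".json")
  write_model(g, pg)
  write_model(sp, ps)
  g2 <- read_model(pg)
  sp2 <- read_model(ps)
  expect_equal(g2$beta, g$beta)
  sensors <- make_obs(paste0("s", 1:5), runif(5, 0, 1e5), runif(5, 0, 1e5),
                      runif(5, 10, 90))
  expect_equal(calibrate(sp2, sensors)$pm25, calibrate(sp, sensors)$pm25,
               tolerance = 1e-12)
})

test_that("humidity can enter the spatial model as a second covariate", {
  net <- generate_network(default_scenario(seed = 6, include_rh = TRUE,
                                           n_sensors = 600, n_stations = 30))
  pairs <- filter_pairs(
    collocate_nearest(net$stations, net$sensors, covariates = "rh"), 2000)
  expect_equal(attr(pairs, "B"), 2L)
  sp <- fit_spatial(pairs, bandwidth = 8e4)
  expect_true(all(c("x1", "x2") %in% names(sp$local_coefficients)))
  out <- calibrate(sp, net$sensors)
  expect_true(all(is.finite(out$pm25)))
})
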