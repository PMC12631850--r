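test_that("lagged cross-covariance matches the brute-force oracle", {
  withr::with_seed(21, {
    x <- rnorm(300); y <- rnorm(300)
  })
  cc <- lagged_cross_covariance(x, y, tr = 0.5, max_lag = 3)
  oracle <- brute_lagged_cov(x, y, max_lag_samples = 6)
  expect_equal(cc$lags, oracle$lags * 0.5)
  expect_equal(cc$cov, oracle$cov, tolerance = 1e-12)
  expect_equal(cc$cor, oracle$cor, tolerance = 1e-12)
  # lag 0 equals the ordinary (1/n) covariance
  expect_equal(cc$cov[7], mean((x - mean(x)) * (y - mean(y))))
})

test_that("autocovariance peaks at zero lag; shifted copies peak at the shift", {
  withr::with_seed(22, x <- as.numeric(stats::filter(rnorm(500), 0.9, "recursive")))
  cc <- lagged_cross_covariance(x, x, tr = 1, max_lag = 10)
  expect_equal(cc$lags[which.max(cc$cov)], 0)

  # periodic toy signal, y = x delayed by exactly 2 samples (circular)
  t <- seq_len(200)
  xs <- sin(2 * pi * t / 25)
  ys <- sin(2 * pi * (t - 2) / 25)
  cc2 <- lagged_cross_covariance(xs, ys, tr = 1, max_lag = 6)
  # x leads y by 2 samples -> curve peaks at -2 under this sign convention
  expect_equal(cc2$lags[which.max(cc2$cor)], -2)
  expect_error(lagged_cross_covariance(xs, ys, tr = 1, max_lag = 120),
               "half the scan")
})

test_that("white-noise pairs yield a flat, small cross-correlation curve", {
  withr::with_seed(23, {
    x <- rnorm(10000); y <- rnorm(10000)
  })
  cc <- lagged_cross_covariance(x, y, tr = 1, max_lag = 5)
  expect_lt(max(abs(cc$cor)), 4 / sqrt(10000))
})

test_that("parabolic interpolation reproduces its closed-form vertex", {
  expect_equal(estimate_lag(c(1, 3, 1), c(-1, 0, 1))$tau, 0)
  est <- estimate_lag(c(1, 3, 2), c(-0.72, 0, 0.72))
  expect_equal(est$tau, 0.72 / 6, tolerance = 1e-12)
  # against dense evaluation of the interpolating polynomial
  p <- function(t) {
    # Lagrange parabola through (-d,1), (0,3), (d,2), d = 0.72
    d <- 0.72
    1 * (t * (t - d)) / (2 * d^2) + 3 * ((t + d) * (d - t)) / d^2 +
      2 * (t * (t + d)) / (2 * d^2)
  }
  grid <- seq(-0.72, 0.72, length.out = 100001)
  expect_equal(est$tau, grid[which.max(p(grid))], tolerance = 1e-4)
  expect_equal(est$peak, max(p(grid)), tolerance = 1e-8)
  # boundary extremum is returned clipped
  expect_equal(estimate_lag(c(3, 2, 1), c(-1, 0, 1))$flag, "clipped")
  # anticorrelated pair: trough of the curve is used and flagged
  tr_est <- estimate_lag(c(-1, -3, -2), c(-1, 0, 1))
  expect_equal(tr_est$flag, "trough")
  expect_equal(tr_est$tau, 0.72 / 6 / 0.72, tolerance = 1e-12)
})

test_that("sub-sample lags are recovered to a fraction of the TR", {
  sim <- make_propagating_bold(2, c(0, 0.36), tr = 0.72, n_timepoints = 2000,
                               snr = Inf, seed = 31)
  td <- time_delay_matrix(sim$ts, threshold = 5)
  expect_lt(abs(td$tau[1, 2] + 0.36), 0.1 * 0.72)
})

test_that("time-delay matrix equals the brute-force double loop entrywise", {
  sim <- make_propagating_bold(5, c(-0.7, -0.2, 0, 0.4, 0.9), tr = 0.72,
                               n_timepoints = 400, snr = 8, seed = 41)
  td <- time_delay_matrix(sim$ts, threshold = 5)
  oracle <- brute_time_delay_matrix(sim$ts$data, tr = 0.72, threshold = 5)
  expect_equal(td$tau, oracle, tolerance = 1e-10)
})

test_that("time-delay matrix invariants hold on arbitrary inputs", {
  withr::with_seed(42, mat <- matrix(rnorm(6 * 150), 6))
  td <- time_delay_matrix(parcellated_ts(mat, tr = 1), threshold = 3)
  expect_equal(td$tau + t(td$tau), matrix(0, 6, 6))
  expect_equal(diag(td$tau), rep(0, 6))
  expect_true(all(abs(td$tau) <= 3 + 1e-12))
  expect_equal(td$peak_cov, t(td$peak_cov))
  expect_true(all(diag(td$peak_cov) >= 0))
})

test_that("a true lag beyond the threshold is clipped and flagged", {
  sim <- make_propagating_bold(2, c(0, 2), tr = 0.5, n_timepoints = 2000,
                               snr = Inf, seed = 43)
  td <- time_delay_matrix(sim$ts, threshold = 1.5)
  expect_lte(abs(td$tau[1, 2]), 1.5)
  expect_equal(td$flags[1, 2], "clipped")
})

test_that("band-limited resampling reconstructs an infra-slow sinusoid", {
  t_in <- seq(0, 598, by = 2)
  ts <- parcellated_ts(rbind(sin(2 * pi * 0.05 * t_in)), tr = 2)
  out <- resample_time_series(ts, target_tr = 0.72)
  t_out <- (seq_len(n_timepoints(out)) - 1) * 0.72
  truth <- sin(2 * pi * 0.05 * t_out)
  interior <- t_out > 60 & t_out < 540
  rms <- sqrt(mean((out$data[1, interior] - truth[interior])^2)) /
    sqrt(mean(truth[interior]^2))
  expect_lt(rms, 0.01)
  expect_equal(resample_time_series(ts, 2)$data, ts$data)
  expect_error(resample_time_series(ts, -1), "positive")
})

test_that("up-sampling preserves lag estimates", {
  # one-sample lag at TR 2.0, re-estimated after up-sampling to 0.5 s
  sim <- make_propagating_bold(2, c(0, 2), tr = 2, n_timepoints = 500,
                               snr = Inf, seed = 44)
  up <- resample_time_series(sim$ts, target_tr = 0.5)
  td <- time_delay_matrix(up, threshold = 5)
  expect_lt(abs(td$tau[1, 2] + 2), 0.25)
})
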