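test_that("sinc detrending removes trends and keeps the rhythm", {
  t <- seq(0, 2880, by = 10)
  # pure linear ramp detrends to (almost) nothing, edges included
  ramp <- lum_trace(t, 5 + 0.02 * t)
  out <- sinc_detrend(ramp, 500)
  expect_lt(max(abs(out$signal)), 0.01 * diff(range(ramp$signal)))

  # constant signal comes back exactly zero
  flat <- lum_trace(t, rep(7, length(t)))
  expect_lt(max(abs(sinc_detrend(flat, 500)$signal)), 1e-9)

  # cosine + ramp: the oscillation survives detrending nearly unchanged
  pure <- cos(2 * pi * t / 200)
  mixed <- lum_trace(t, pure + 0.01 * t + 3)
  det <- sinc_detrend(mixed, 500)
  expect_gt(stats::cor(det$signal, pure), 0.99)

  expect_error(sinc_detrend(lum_trace(t, pure), 15), "twice the sampling")
})

test_that("amplitude normalization flattens a slowly damped envelope", {
  t <- seq(0, 2880, by = 10)
  damped <- lum_trace(t, exp(-0.001 * t) * cos(2 * pi * t / 200))
  norm <- amplitude_normalize(damped, window = 200)
  pk <- norm$signal[which(diff(sign(diff(norm$signal))) == -2) + 1]
  interior <- pk[2:(length(pk) - 1)]
  expect_lt((max(interior) - min(interior)) / mean(interior), 0.10)

  # already unit-amplitude cosine: near identity away from the edges
  unitc <- lum_trace(t, cos(2 * pi * t / 200))
  out <- amplitude_normalize(unitc, window = 200)
  mid <- t > 300 & t < 2580
  expect_equal(out$signal[mid], unitc$signal[mid], tolerance = 0.1)

  # white noise: epsilon guard keeps the output bounded
  set.seed(2)
  wn <- lum_trace(t, stats::rnorm(length(t)))
  expect_true(all(is.finite(amplitude_normalize(wn, window = 200)$signal)))
})

test_that("wavelet estimator recovers generator periods to grid resolution", {
  for (cfg in list(list(p = 153, dur = 2880, cut = 250),
                   list(p = 388, dur = 4320, cut = 500))) {
    tr <- gen_oscillation_trace(osc_trace_spec(period = cfg$p, duration = cfg$dur,
                                               drift_slope = 2e-4))
    est <- estimate_period(tr, detrend_config(cfg$cut))
    expect_lt(abs(est$period - cfg$p), grid_step())
    expect_false(est$low_power)
    expect_true(all(est$power_spectrum$power >= 0))
    expect_true(est$period >= 100 && est$period <= 500)
  }
})

test_that("period estimate is invariant to affine signal transforms", {
  tr <- gen_oscillation_trace(osc_trace_spec(period = 236, duration = 2880,
                                             noise_sd = 0.05, seed = 4))
  base <- estimate_period(tr, detrend_config(500))$period
  shifted <- lum_trace(tr$time, 3.7 * tr$signal + 120)
  expect_equal(estimate_period(shifted, detrend_config(500))$period, base)
})

test_that("white noise is flagged as having no reliable rhythm", {
  set.seed(8)
  wn <- lum_trace(seq(0, 2880, by = 10), stats::rnorm(289))
  est <- estimate_period(wn, detrend_config(500))
  expect_true(est$low_power)
})

test_that("half-life estimator is exact on clean exponential decay", {
  tr <- gen_decay_trace(decay_trace_spec(halflife = 24, duration = 200, dt = 10))
  est <- estimate_halflife(tr)
  expect_equal(est$halflife, 24, tolerance = 1e-9)
  expect_lt(est$slope, 0)
  expect_equal(est$halflife, -1 / est$slope, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-9)
})

test_that("RANSAC window excludes the residual-mRNA plateau", {
  tr <- gen_decay_trace(decay_trace_spec(halflife = 46, duration = 900,
                                         plateau_min = 120, noise_sd = 0.01, seed = 1))
  est <- estimate_halflife(tr, seed = 0)
  expect_lt(abs(est$halflife - 46) / 46, 0.05)
  expect_gte(est$inlier_window[["t_start"]], 120)
})

test_that("half-life is invariant under signal scaling and flat traces error", {
  tr <- gen_decay_trace(decay_trace_spec(halflife = 33, duration = 700,
                                         plateau_min = 60, noise_sd = 0.01, seed = 3))
  a <- estimate_halflife(tr, seed = 0)$halflife
  scaled <- lum_trace(tr$time, 57.3 * tr$signal)
  expect_equal(estimate_halflife(scaled, seed = 0)$halflife, a, tolerance = 1e-9)

  flat <- lum_trace(seq(0, 500, 10), rep(100, 51))
  expect_error(estimate_halflife(flat), "no-decay")
  expect_error(estimate_halflife(lum_trace(1:20, c(0, 2:20))), "positive")
})

test_that("cross-correlation delay is exact for identical and shifted traces", {
  tr <- gen_oscillation_trace(osc_trace_spec(period = 153, duration = 2880))
  self <- estimate_delay(tr, tr, max_lag = 120, config = detrend_config(250))
  expect_equal(self$delay, 0)
  expect_gt(self$peak_correlation, 0.999)
  expect_false(self$unreliable)

  # sub-sample recovery across lags that are not grid multiples
  for (lag in c(15, 40, 77.3)) {
    pair <- gen_dual_reporter(dual_reporter_spec(period = 238, duration = 2880, lag = lag))
    est <- estimate_delay(pair$without_intron, pair$with_intron,
                          max_lag = 200, config = detrend_config(500))
    expect_lt(abs(est$delay - lag), 5) # dt / 2
  }
})

test_that("delay estimator flags weakly correlated channel pairs", {
  set.seed(21)
  t <- seq(0, 2880, by = 10)
  a <- lum_trace(t, stats::rnorm(length(t)))
  b <- lum_trace(t, stats::rnorm(length(t)))
  est <- estimate_delay(a, b, max_lag = 120, detrend = FALSE)
  expect_true(est$unreliable)
})

test_that("delay is recovered at 5% noise with sub-sample RMSE below dt", {
  errs <- vapply(1:100, function(s) {
    pair <- gen_dual_reporter(dual_reporter_spec(period = 238, duration = 2880,
                                                 lag = 37, noise_sd = 0.05, seed = s))
    estimate_delay(pair$without_intron, pair$with_intron,
                   max_lag = 200, config = detrend_config(500))$delay - 37
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 10)
})

test_that("half-life RMSE stays below 10% at 5% noise", {
  errs <- vapply(1:100, function(s) {
    tr <- gen_decay_trace(decay_trace_spec(halflife = 46, duration = 900,
                                           plateau_min = 120, noise_sd = 0.05, seed = s))
    estimate_halflife(tr, seed = 0)$halflife - 46
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 4.6)
})

test_that("first-peak normalization anchors time zero and unit amplitude", {
  t <- seq(0, 2000, by = 10)
  # starts exactly on a peak
  atpeak <- lum_trace(t, 2 * cos(2 * pi * t / 200))
  norm <- first_peak_normalize(atpeak)
  expect_equal(norm$time[1], 0)
  expect_equal(norm$signal[1], 1)

  # shifted cosine: first interior peak maps to zero
  shifted <- lum_trace(t, cos(2 * pi * (t - 70) / 200))
  norm2 <- first_peak_normalize(shifted)
  expect_equal(norm2$time[which.min(abs(norm2$time))], 0)
  expect_equal(max(norm2$signal[norm2$time == 0]), 1)

  expect_error(first_peak_normalize(lum_trace(t, rep(1, length(t)))), "no oscillation")
})

test_that("irregular sampling is resampled onto a uniform grid", {
  set.seed(6)
  t <- sort(stats::runif(200, 0, 2000))
  tr <- lum_trace(t, cos(2 * pi * t / 200))
  expect_lt(max(abs(diff(diff(tr$time)))), 1e-9)
})
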