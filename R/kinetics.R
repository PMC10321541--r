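#' Detrending and period-scan configuration
#'
#' Mirrors the wavelet workflow used for the reporter traces: a windowed-sinc
#' low-pass filter removes slow drift (cutoff 500 min by default; 250 min is
#' the choice for the fast rabbit clock so that the oscillation itself is not
#' absorbed into the trend), a sliding-window envelope normalizes amplitude,
#' and a Morlet wavelet scan over 100-500 min extracts the period.
#'
#' @param cutoff_period Sinc low-pass cutoff in minutes (also the default
#'   amplitude-normalization window).
#' @param window Amplitude-envelope window in minutes; defaults to
#'   `cutoff_period`.
#' @param period_scan `c(min_period, max_period, n_grid)` for the wavelet
#'   scan.
#' @return A list of class `detrend_config`.
#' @export
detrend_config <- function(cutoff_period = 500, window = cutoff_period,
                           period_scan = c(100, 500, 200)) {
  if (cutoff_period <= 0 || window <= 0) {
    stop("cutoff and window must be > 0", call. = FALSE)
  }
  if (length(period_scan) != 3L || period_scan[1L] <= 0 ||
      period_scan[1L] >= period_scan[2L] || period_scan[3L] < 2) {
    stop("`period_scan` must be c(min, max, n) with 0 < min < max, n >= 2",
         call. = FALSE)
  }
  structure(
    list(cutoff_period = cutoff_period, window = window,
         period_scan = period_scan),
    class = "detrend_config"
  )
}

#' Sinc (low-pass) detrending of a luminescence trace
#'
#' Estimates the slow trend as the least-squares line plus the low-pass
#' component of the residual, obtained by convolving with a
#' Blackman-windowed sinc FIR kernel of cutoff frequency `1/cutoff_period`,
#' and subtracts it. Removing the fitted line first makes a pure ramp
#' detrend to exactly zero and keeps the filter's reflection padding from
#' bending around ramps or oscillation peaks at the edges. Kernel length is
#' `min(n, 3 * cutoff_period / dt)`, odd; edges are handled by even
#' reflection of the line-free residual.
#'
#' @param trace A [lum_trace()], uniformly sampled.
#' @param cutoff_period Cutoff in minutes; must exceed `2 * dt`.
#' @return A detrended [lum_trace()] with mean approximately zero.
#' @export
#' @examples
#' tr <- gen_oscillation_trace(osc_trace_spec(200, 2000, drift_slope = 0.01))
#' dtr <- sinc_detrend(tr, 500)
sinc_detrend <- function(trace, cutoff_period = 500) {
  stopifnot(inherits(trace, "lum_trace"))
  dt <- trace_dt(trace)
  if (cutoff_period <= 2 * dt) {
    stop("`cutoff_period` must exceed twice the sampling interval", call. = FALSE)
  }
  n <- nrow(trace)
  L <- min(if (n %% 2L == 1L) n else n - 1L, floor(3 * cutoff_period / dt))
  if (L %% 2L == 0L) L <- L - 1L
  if (L < 5L) stop("trace too short for the sinc kernel", call. = FALSE)
  # the OLS line carries ramps and offsets exactly; the sinc low-pass only
  # has to track the slow curvature of the line-free residual
  line <- stats::lm.fit(cbind(1, trace$time), trace$signal)$fitted.values
  x <- trace$signal - line
  kern <- sinc_kernel(L, fc = dt / cutoff_period)
  half <- (L - 1L) %/% 2L
  padded <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  trend <- stats::convolve(padded, rev(kern), type = "filter")
  lum_trace(trace$time, x - trend)
}

# Blackman-windowed sinc low-pass kernel, length L (odd), cutoff fc in
# cycles/sample, normalized to unit DC gain
sinc_kernel <- function(L, fc) {
  m <- seq_len(L) - 1L
  center <- (L - 1L) / 2
  s <- 2 * fc * (m - center)
  h <- ifelse(s == 0, 1, sin(pi * s) / (pi * s))
  w <- 0.42 - 0.5 * cos(2 * pi * m / (L - 1L)) + 0.08 * cos(4 * pi * m / (L - 1L))
  hw <- h * w
  hw / sum(hw)
}

#' Sliding-window amplitude normalization
#'
#' Divides a detrended signal by its local amplitude envelope, estimated as
#' the sliding-window standard deviation times sqrt(2) (the SD of a unit
#' sinusoid is 1/sqrt(2)), so a slowly damped oscillation comes out with
#' near-constant unit amplitude. Windows with (numerically) zero variance
#' are floored at a small epsilon and flagged via attribute
#' `flat_windows`.
#'
#' @param trace A detrended [lum_trace()].
#' @param window Envelope window in minutes.
#' @param eps Variance floor guarding against division blow-up.
#' @return A normalized [lum_trace()].
#' @export
amplitude_normalize <- function(trace, window = 500, eps = 1e-8) {
  stopifnot(inherits(trace, "lum_trace"))
  dt <- trace_dt(trace)
  k <- max(3L, round(window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  x <- trace$signal
  n <- length(x)
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  half <- (k - 1L) %/% 2L
  # even reflection padding, then running SD from running first/second moments
  padded <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  ones <- rep(1 / k, k)
  m1 <- stats::convolve(padded, ones, type = "filter")
  m2 <- stats::convolve(padded^2, ones, type = "filter")
  v <- pmax(m2 - m1^2, 0)
  env <- sqrt(2 * v)
  flat <- env < sqrt(eps)
  out <- lum_trace(trace$time, x / pmax(env, sqrt(eps)))
  attr(out, "flat_windows") <- sum(flat)
  out
}

#' Morlet wavelet period estimate of an oscillatory trace
#'
#' Runs the full pipeline on a raw trace: sinc detrending, amplitude
#' normalization, then a continuous Morlet wavelet transform (center
#' frequency `omega0 = 2*pi`) over a linear period grid. Wavelet power is
#' averaged over time at each period (the time-averaged, Fourier-like
#' spectrum), excluding samples inside the cone of influence, and the
#' grid period with maximum average power is returned.
#'
#' @param trace A [lum_trace()].
#' @param config A [detrend_config()].
#' @param detrend If `FALSE` the trace is assumed already detrended and
#'   normalized.
#' @return A list of class `period_estimate`: `period` (min), `power` (max
#'   time-averaged power), `power_spectrum` (data frame `period`, `power`),
#'   `low_power` and `boundary` flags, `method = "morlet-cwt"`.
#' @export
#' @examples
#' tr <- gen_oscillation_trace(osc_trace_spec(period = 153, duration = 2880))
#' estimate_period(tr, detrend_config(cutoff_period = 250))$period
estimate_period <- function(trace, config = detrend_config(), detrend = TRUE) {
  stopifnot(inherits(trace, "lum_trace"), inherits(config, "detrend_config"))
  if (detrend) {
    trace <- sinc_detrend(trace, config$cutoff_period)
    trace <- amplitude_normalize(trace, config$window)
  }
  dt <- trace_dt(trace)
  x <- trace$signal - mean(trace$signal)
  n <- length(x)
  periods <- seq(config$period_scan[1L], config$period_scan[2L],
                 length.out = config$period_scan[3L])

  omega0 <- 2 * pi
  # Fourier-period <-> scale conversion for the Morlet wavelet
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods / fourier_factor

  # analytic Morlet CWT via FFT (Torrence & Compo normalization)
  npad <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, rep(0, npad - n)))
  omega <- 2 * pi * c(0, seq_len(npad - 1)) / (npad * dt)
  omega[omega > pi / dt] <- omega[omega > pi / dt] - 2 * pi / dt

  var_x <- stats::var(x)
  if (var_x == 0) var_x <- 1
  avg_power <- numeric(length(scales))
  tgrid <- (seq_len(n) - 1) * dt
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi_hat <- ifelse(
      omega > 0,
      pi^(-0.25) * exp(-(s * omega - omega0)^2 / 2),
      0
    ) * sqrt(2 * pi * s / dt)
    w <- stats::fft(xf * Conj(psi_hat), inverse = TRUE)[seq_len(n)] / npad
    # cone of influence: e-folding time sqrt(2) * s from each edge
    coi <- sqrt(2) * s
    inside <- tgrid >= coi & tgrid <= (tgrid[n] - coi)
    pw <- Mod(w)^2 / var_x
    avg_power[i] <- if (any(inside)) mean(pw[inside]) else 0
  }

  best <- which.max(avg_power)
  res <- list(
    period = periods[best],
    power = avg_power[best],
    power_spectrum = data.frame(period = periods, power = avg_power),
    low_power = avg_power[best] < 10 * stats::median(avg_power),
    boundary = best == 1L || best == length(periods),
    method = "morlet-cwt"
  )
  class(res) <- "period_estimate"
  res
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("<period_estimate> %.2f min (power %.2f%s)\n", x$period, x$power,
              if (x$low_power) ", LOW POWER" else ""))
  invisible(x)
}

#' RANSAC configuration for the half-life estimator
#'
#' @param n_iter Number of random 2-point hypotheses.
#' @param min_samples Minimal sample size per hypothesis (2: a line).
#' @param residual_threshold Absolute residual (log2 units) for inlier
#'   classification; `NULL` (default) uses `1.5 x` the MAD of the
#'   first-differenced log2 signal, floored at 1e-6 so exact data still
#'   classifies.
#' @param min_inlier_frac Minimal fraction of candidate points that must be
#'   inliers for a stable fit.
#' @return A list of class `ransac_config`.
#' @export
ransac_config <- function(n_iter = 200, min_samples = 2,
                          residual_threshold = NULL,
                          min_inlier_frac = 0.25) {
  structure(
    list(n_iter = n_iter, min_samples = min_samples,
         residual_threshold = residual_threshold,
         min_inlier_frac = min_inlier_frac),
    class = "ransac_config"
  )
}

#' Protein half-life from a decay trace (robust log-linear fit)
#'
#' Implements the degradation-assay analysis: the signal is log2-transformed
#' and the most linear part of the decay curve is located with a RANSAC line
#' search, so that the early plateau (residual mRNA still being translated)
#' and late noise-floor points are excluded automatically. The candidate
#' window starts at the global signal maximum; random two-point lines are
#' scored by their inlier consensus (absolute residual below the threshold),
#' and the final slope is an ordinary least-squares refit on the largest
#' contiguous inlier segment. The half-life is `-1/slope` (slope in log2
#' units per minute).
#'
#' @param trace A strictly positive [lum_trace()] with >= 8 samples.
#' @param seed Integer seed for the RANSAC draws (default 0).
#' @param config A [ransac_config()].
#' @return A list of class `halflife_estimate`: `halflife` (min), `slope`
#'   (log2/min), `inlier_window` (`c(t_start, t_end)`), `n_inliers`,
#'   `r_squared` (on the refit segment), `seed`.
#' @export
#' @examples
#' tr <- gen_decay_trace(decay_trace_spec(halflife = 46, duration = 900,
#'                                        plateau_min = 120, noise_sd = 0.01, seed = 1))
#' estimate_halflife(tr)$halflife
estimate_halflife <- function(trace, seed = 0L, config = ransac_config()) {
  stopifnot(inherits(trace, "lum_trace"))
  if (any(trace$signal <= 0)) {
    stop("decay trace must be strictly positive", call. = FALSE)
  }
  if (nrow(trace) < 8L) stop("need at least 8 samples", call. = FALSE)

  # later time points only: start the candidate window at the signal maximum
  start <- which.max(trace$signal)
  tt <- trace$time[start:nrow(trace)]
  y <- log2(trace$signal[start:nrow(trace)])
  m <- length(y)
  if (m < 4L) stop("too few points after the signal maximum", call. = FALSE)

  thr <- config$residual_threshold
  if (is.null(thr)) thr <- max(1.5 * stats::mad(diff(y)), 1e-6)
  min_inliers <- max(3L, ceiling(config$min_inlier_frac * m))

  best <- with_seed(seed, {
    best <- list(n = -1L, inliers = NULL)
    for (it in seq_len(config$n_iter)) {
      idx <- sample.int(m, config$min_samples)
      if (tt[idx[1L]] == tt[idx[2L]]) next
      sl <- (y[idx[2L]] - y[idx[1L]]) / (tt[idx[2L]] - tt[idx[1L]])
      ic <- y[idx[1L]] - sl * tt[idx[1L]]
      inl <- abs(y - (ic + sl * tt)) <= thr
      if (sl < 0 && sum(inl) > best$n) best <- list(n = sum(inl), inliers = inl)
    }
    best
  })
  if (best$n < min_inliers) {
    if (best$n < 0L) stop("no decaying segment found (no-decay)", call. = FALSE)
    stop(sprintf("unstable fit: only %d inliers (need >= %d)", best$n, min_inliers),
         call. = FALSE)
  }

  # largest contiguous run of inliers, then ordinary least-squares refit
  r <- rle(best$inliers)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pick <- runs[which.max(r$lengths[runs])]
  seg <- starts[pick]:ends[pick]

  fit <- stats::lm(y[seg] ~ tt[seg])
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    stop("fitted slope is non-negative (no-decay)", call. = FALSE)
  }
  res <- list(
    halflife = -1 / slope,
    slope = slope,
    inlier_window = c(t_start = tt[seg[1L]], t_end = tt[seg[length(seg)]]),
    n_inliers = length(seg),
    # suppress the "essentially perfect fit" note on noiseless segments
    r_squared = suppressWarnings(summary(fit)$r.squared),
    seed = seed
  )
  class(res) <- "halflife_estimate"
  res
}

#' @export
print.halflife_estimate <- function(x, ...) {
  cat(sprintf("<halflife_estimate> %.2f min (slope %.4f log2/min, %d inliers, R2 %.3f)\n",
              x$halflife, x$slope, x$n_inliers, x$r_squared))
  invisible(x)
}

#' Intron delay by cross-correlation of a dual-reporter pair
#'
#' Estimates the phase lag of the intron-containing reporter behind the
#' intronless one as the argmax of their normalized cross-correlation over
#' non-negative lags (intron processing can only delay), refined to
#' sub-sample resolution by parabolic interpolation around the discrete
#' peak. Both traces are sinc-detrended and amplitude-normalized first
#' (disable with `detrend = FALSE`). No reporter-maturation correction is
#' applied to the returned lag.
#'
#' @param trace_a Intronless-reporter [lum_trace()] (leading channel).
#' @param trace_b Intron-containing reporter [lum_trace()] on the same grid
#'   (resampled onto `trace_a`'s grid otherwise).
#' @param max_lag Largest lag scanned, minutes.
#' @param config A [detrend_config()] used for pre-processing.
#' @param detrend If `FALSE`, traces are used as supplied.
#' @return A list of class `delay_estimate`: `delay` (min),
#'   `peak_correlation`, `lag_curve` (data frame `lag`, `correlation`),
#'   `unreliable` flag (peak correlation < 0.2).
#' @export
#' @examples
#' pair <- gen_dual_reporter(dual_reporter_spec(period = 153, duration = 2880, lag = 24))
#' estimate_delay(pair$without_intron, pair$with_intron, max_lag = 120)$delay
estimate_delay <- function(trace_a, trace_b, max_lag = 120,
                           config = detrend_config(), detrend = TRUE) {
  stopifnot(inherits(trace_a, "lum_trace"), inherits(trace_b, "lum_trace"))
  if (!isTRUE(all.equal(trace_a$time, trace_b$time))) {
    trace_b <- lum_trace(
      trace_a$time,
      stats::approx(trace_b$time, trace_b$signal, xout = trace_a$time, rule = 2)$y
    )
  }
  if (detrend) {
    trace_a <- amplitude_normalize(sinc_detrend(trace_a, config$cutoff_period), config$window)
    trace_b <- amplitude_normalize(sinc_detrend(trace_b, config$cutoff_period), config$window)
  }
  dt <- trace_dt(trace_a)
  a <- trace_a$signal
  b <- trace_b$signal
  n <- length(a)
  kmax <- min(floor(max_lag / dt), n - 3L)
  lags <- 0:kmax
  cc <- vapply(lags, function(k) {
    stats::cor(a[seq_len(n - k)], b[seq.int(k + 1L, n)])
  }, numeric(1L))

  best <- which.max(cc)
  delay <- lags[best] * dt
  # parabolic refinement through the three points around the discrete peak
  if (best > 1L && best < length(cc)) {
    y1 <- cc[best - 1L]; y2 <- cc[best]; y3 <- cc[best + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) delay <- delay + dt * 0.5 * (y1 - y3) / denom
  }
  res <- list(
    delay = max(delay, 0),
    peak_correlation = cc[best],
    lag_curve = data.frame(lag = lags * dt, correlation = cc),
    unreliable = cc[best] < 0.2
  )
  class(res) <- "delay_estimate"
  res
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("<delay_estimate> %.2f min (peak correlation %.3f%s)\n",
              x$delay, x$peak_correlation,
              if (x$unreliable) ", UNRELIABLE" else ""))
  invisible(x)
}

#' Normalize a trace to its first oscillation peak
#'
#' Display-oriented normalization: time is shifted so the first detected
#' peak sits at t = 0 and the signal is scaled so that peak equals 1.
#'
#' @param trace A [lum_trace()].
#' @param min_prominence_frac Peak prominence floor as a fraction of the
#'   signal range.
#' @return A rescaled [lum_trace()].
#' @export
first_peak_normalize <- function(trace, min_prominence_frac = 0.05) {
  stopifnot(inherits(trace, "lum_trace"))
  x <- trace$signal
  pk <- find_peaks(x, min_prominence = min_prominence_frac * diff(range(x)))
  # a recording that starts exactly on a peak has no interior maximum there
  if (x[1L] > x[2L]) pk <- c(1L, pk)
  if (!length(pk)) stop("no oscillation peak detected", call. = FALSE)
  p1 <- pk[1L]
  if (x[p1] == 0) stop("first peak has zero amplitude", call. = FALSE)
  lum_trace(trace$time - trace$time[p1], x / x[p1])
}
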