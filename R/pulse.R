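#' Construct a multichannel pulse trace
#'
#' A uniformly sampled record from the two-sensor trough: time in s, the two
#' Wilhelmy-plate pressure channels `p1` and `p2` in mN/m, optionally the
#' Kelvin-probe surface potential `v_total` in mV and the two fluorescence
#' emission channels `i535`, `i605` (arbitrary units). Sensor geometry is
#' carried as attributes.
#'
#' @param data A data frame with a `time` column on a uniform grid (relative
#'   deviations beyond 1 ppm of the step are rejected) plus channel columns
#'   `p1`, `p2` and optionally `v_total`, `i535`, `i605`.
#' @param sampling_rate Samples per second; inferred from `time` if `NULL`.
#' @param sensor_separation Distance between the two pressure sensors in m
#'   (default 0.15 m).
#' @param excitation_distance Optional distance from excitation site to
#'   sensor 1 in m.
#' @return A `pulse_trace` tibble.
#' @export
pulse_trace <- function(data, sampling_rate = NULL, sensor_separation = 0.15,
                        excitation_distance = NULL) {
  data <- as_tibble(data)
  if (!all(c("time", "p1", "p2") %in% names(data))) {
    abort("`data` needs columns `time`, `p1` and `p2`.")
  }
  if (nrow(data) < 10L) abort("A pulse trace needs at least 10 samples.")
  dt <- diff(data$time)
  if (any(dt <= 0)) abort("`time` must be strictly increasing.")
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
    abort("`time` must be uniformly sampled (within 1 ppm).")
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / mean(dt)
  if (sensor_separation <= 0) abort("`sensor_separation` must be > 0 (m).")

  keep <- intersect(c("time", "p1", "p2", "v_total", "i535", "i605"), names(data))
  out <- data[keep]
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "sensor_separation") <- sensor_separation
  attr(out, "excitation_distance") <- excitation_distance
  class(out) <- c("pulse_trace", class(out))
  out
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf(
    "<pulse_trace> %d samples @ %g Hz, channels: %s, sensor separation %g m\n",
    nrow(x), attr(x, "sampling_rate"),
    paste(setdiff(names(x), "time"), collapse = ", "),
    attr(x, "sensor_separation")
  ))
  NextMethod()
}

# centred moving average with replicated edges (length preserving)
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) abort("`smooth_window` must be odd.")
  pad <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[
    seq(pad + 1L, pad + length(x))]
}

# baseline statistics from the leading fraction of a channel
channel_baseline <- function(x, baseline_fraction) {
  n0 <- max(2L, floor(length(x) * baseline_fraction))
  list(mean = mean(x[seq_len(n0)]), sd = sd(x[seq_len(n0)]), n = n0)
}

# signed dominant excursion of a channel relative to its baseline;
# errors when no excursion rises above the noise floor
dominant_pulse <- function(x, baseline_fraction = 0.1, label = "channel") {
  bl <- channel_baseline(x, baseline_fraction)
  dev <- x - bl$mean
  i_peak <- which.max(abs(dev))
  amp <- dev[i_peak]
  floor_amp <- max(5 * bl$sd, 1e4 * .Machine$double.eps * max(abs(x), 1))
  if (abs(amp) <= floor_amp) {
    abort(sprintf("No pulse found in %s: peak excursion %.3g does not exceed 5x the baseline noise.",
                  label, abs(amp)))
  }
  list(baseline = bl$mean, baseline_sd = bl$sd, i_peak = i_peak, amplitude = amp)
}

# first crossing of frac*|amplitude| on the pulse's leading edge, with
# linear sub-sample interpolation; returns a fractional index
leading_edge_index <- function(dev, i_peak, amplitude, frac) {
  thr <- frac * abs(amplitude)
  s <- sign(amplitude)
  below <- which(s * dev[seq_len(i_peak)] < thr)
  i_lo <- if (length(below)) max(below) else return(1)
  if (i_lo == i_peak) return(i_peak)
  y0 <- s * dev[i_lo]; y1 <- s * dev[i_lo + 1L]
  i_lo + (thr - y0) / (y1 - y0)
}

# lag (in samples, sub-sample refined) of y relative to x, via FFT circular
# cross-correlation; traces are baseline-relative so wraparound is benign
xcorr_lag <- function(x, y) {
  n <- length(x)
  cc <- stats::convolve(y, x, conj = TRUE, type = "circular")
  k <- which.max(cc)
  lag <- if (k - 1 > n / 2) k - 1 - n else k - 1
  # parabolic refinement around the discrete maximum (circular neighbours)
  y0 <- cc[if (k == 1L) n else k - 1L]
  y1 <- cc[k]
  y2 <- cc[if (k == n) 1L else k + 1L]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) > 0) 0.5 * (y0 - y2) / denom else 0
  lag + max(min(delta, 0.5), -0.5)
}

#' Arrival times of a pulse at the two pressure sensors
#'
#' Locates the single dominant pulse in each pressure channel and returns
#' its arrival time at sensor 1 and sensor 2. Two criteria are offered:
#' `"threshold"` takes the first leading-edge crossing of
#' `threshold_fraction` times the peak excursion (measured from the
#' pre-arrival baseline, the mean of the leading 10% of samples);
#' `"xcorr"` takes the inter-sensor delay from the cross-correlation
#' maximum with parabolic sub-sample refinement and anchors it at the
#' channel-1 threshold arrival. Both agree for well-separated pulses; the
#' choice matters only for strongly distorted wavefronts.
#'
#' @param trace A [pulse_trace()].
#' @param method `"threshold"` (default) or `"xcorr"`.
#' @param threshold_fraction Fraction of the peak excursion defining the
#'   leading-edge arrival (default 0.5).
#' @param baseline_fraction Leading fraction of samples treated as
#'   pre-arrival baseline (default 0.1).
#' @param smooth_window Odd moving-average window (samples) applied to both
#'   channels before detection; 1 (default) leaves the raw signal untouched.
#'   A window spanning a few tens of milliseconds stabilises arrival and
#'   amplitude estimates on noisy records at negligible cost in bias.
#' @return A named list `t1`, `t2` (s). Errors if either channel holds no
#'   pulse at least 5x above its baseline noise, or if the implied delay is
#'   not positive.
#' @export
detect_arrivals <- function(trace, method = c("threshold", "xcorr"),
                            threshold_fraction = 0.5, baseline_fraction = 0.1,
                            smooth_window = 1L) {
  if (!inherits(trace, "pulse_trace")) abort("`trace` must be a `pulse_trace`.")
  method <- match.arg(method)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1).")
  }
  dt <- 1 / attr(trace, "sampling_rate")

  p1 <- moving_average(trace$p1, smooth_window)
  p2 <- moving_average(trace$p2, smooth_window)
  d1 <- dominant_pulse(p1, baseline_fraction, "p1")
  d2 <- dominant_pulse(p2, baseline_fraction, "p2")
  dev1 <- p1 - d1$baseline
  dev2 <- p2 - d2$baseline

  i1 <- leading_edge_index(dev1, d1$i_peak, d1$amplitude, threshold_fraction)
  t1 <- trace$time[1] + (i1 - 1) * dt

  if (method == "threshold") {
    i2 <- leading_edge_index(dev2, d2$i_peak, d2$amplitude, threshold_fraction)
    t2 <- trace$time[1] + (i2 - 1) * dt
  } else {
    lag <- xcorr_lag(dev1, dev2)
    t2 <- t1 + lag * dt
  }

  if (t2 - t1 <= 0) {
    abort("Non-positive inter-sensor delay: the pulse does not propagate from sensor 1 to sensor 2.")
  }
  list(t1 = t1, t2 = t2)
}

# single-exponential relaxation time of the post-peak return to baseline
fit_relaxation <- function(time, dev, i_peak, amplitude) {
  post <- seq(i_peak, length(dev))
  s <- sign(amplitude)
  rec <- which(s * dev[post] <= 0.1 * abs(amplitude))   # 90% recovered
  i_end <- if (length(rec)) post[min(rec)] else length(dev)
  idx <- seq(i_peak, i_end)
  y <- s * dev[idx]
  ok <- y > 0
  if (sum(ok) < 5L) return(NA_real_)
  tt <- time[idx][ok] - time[i_peak]
  fit <- tryCatch(lm(log(y[ok]) ~ tt), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  unname(-1 / slope)
}

#' Pulse features from a two-sensor trace
#'
#' Summarises the dominant pulse: arrival times, inter-sensor delay, the
#' propagation velocity `separation / delay`, signed amplitudes at both
#' sensors (extremum minus pre-arrival baseline; an expansion pulse — a
#' pressure decrease — has negative amplitude), the damping ratio
#' `amplitude_2 / amplitude_1`, and the single-exponential relaxation time
#' of the return to equilibrium at sensor 1.
#'
#' @inheritParams detect_arrivals
#' @return A one-row `pulse_features` tibble with columns `t_arrival_1`,
#'   `t_arrival_2`, `delay` (s), `velocity` (m/s), `amplitude_1`,
#'   `amplitude_2` (mN/m), `damping_ratio`, `relaxation_time` (s), `method`.
#' @examples
#' truth <- synthetic_truth(pulse_velocity = 0.6, noise_sd = c(p1 = 0, p2 = 0))
#' tr <- make_pulse_traces(truth, seed = 1)
#' pulse_features(tr)
#' @export
pulse_features <- function(trace, method = c("threshold", "xcorr"),
                           threshold_fraction = 0.5, baseline_fraction = 0.1,
                           smooth_window = 1L) {
  method <- match.arg(method)
  arr <- detect_arrivals(trace, method, threshold_fraction, baseline_fraction,
                         smooth_window)

  p1 <- moving_average(trace$p1, smooth_window)
  p2 <- moving_average(trace$p2, smooth_window)
  d1 <- dominant_pulse(p1, baseline_fraction, "p1")
  d2 <- dominant_pulse(p2, baseline_fraction, "p2")
  delay <- arr$t2 - arr$t1
  sep <- attr(trace, "sensor_separation")

  out <- tibble(
    t_arrival_1 = arr$t1,
    t_arrival_2 = arr$t2,
    delay = delay,
    velocity = sep / delay,
    amplitude_1 = d1$amplitude,
    amplitude_2 = d2$amplitude,
    damping_ratio = d2$amplitude / d1$amplitude,
    relaxation_time = fit_relaxation(trace$time, p1 - d1$baseline,
                                     d1$i_peak, d1$amplitude),
    method = method
  )
  class(out) <- c("pulse_features", class(out))
  out
}

#' @describeIn pulse_features Features in long `term`/`estimate` form.
#' @param x A `pulse_features` row.
#' @param ... Unused.
#' @export
tidy.pulse_features <- function(x, ...) {
  num <- x[vapply(x, is.numeric, logical(1))]
  tibble(term = names(num), estimate = as.numeric(num[1, ]))
}

#' Quasi-static prediction of the electrical pulse
#'
#' Given the quasi-static `V_total(pi)` relation from
#' [potential_pressure_map()], predicts the surface-potential change that
#' accompanies a pressure pulse of given amplitude:
#' `V_total(p_baseline + amplitude) - V_total(p_baseline)`.
#'
#' @param map A [potential_pressure_map()].
#' @param p_baseline Baseline lateral pressure in mN/m.
#' @param amplitude Signed pulse amplitude in mN/m (negative for expansion).
#' @return Predicted surface-potential change in mV.
#' @export
quasi_static_potential_prediction <- function(map, p_baseline, amplitude) {
  predict(map, p_baseline + amplitude) - predict(map, p_baseline)
}
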