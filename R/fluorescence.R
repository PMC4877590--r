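#' Construct a ratiometric calibration line
#'
#' Linear map between the fluorescence intensity ratio
#' `I_R = I_535 / I_605` and pH, valid only over the pH and lateral-pressure
#' ranges it was measured in. Ratiometric calibrations are dye- and
#' environment-specific and must not be extrapolated.
#'
#' @param slope Ratio units per pH unit; must be non-zero.
#' @param intercept Ratio at pH 0.
#' @param valid_ph_range Length-2 numeric, the pH range the calibration
#'   covers.
#' @param valid_pressure_range Length-2 numeric, the lateral-pressure range
#'   (mN/m) over which the ratio is pressure-independent.
#' @param sigma Residual standard deviation of the calibration fit.
#' @return A `calibration_line` object.
#' @examples
#' calibration_line(0.6, -1.9, c(6.5, 7.5), c(5, 8))
#' @export
calibration_line <- function(slope, intercept,
                             valid_ph_range,
                             valid_pressure_range = c(5, 8),
                             sigma = 0) {
  if (!is.numeric(slope) || slope == 0) abort("`slope` must be non-zero.")
  if (length(valid_ph_range) != 2L || diff(valid_ph_range) <= 0) {
    abort("`valid_ph_range` must be an increasing length-2 range.")
  }
  if (length(valid_pressure_range) != 2L || diff(valid_pressure_range) <= 0) {
    abort("`valid_pressure_range` must be an increasing length-2 range.")
  }
  structure(
    list(slope = slope, intercept = intercept,
         valid_ph_range = as.numeric(valid_ph_range),
         valid_pressure_range = as.numeric(valid_pressure_range),
         sigma = sigma),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(
    "<calibration_line> I_R = %.4g + %.4g * pH, valid pH [%g, %g], pressure [%g, %g] mN/m\n",
    x$intercept, x$slope, x$valid_ph_range[1], x$valid_ph_range[2],
    x$valid_pressure_range[1], x$valid_pressure_range[2]
  ))
  invisible(x)
}

#' Fit a ratiometric pH calibration
#'
#' Ordinary least-squares line through measured `(pH, I_R)` points. The
#' validity ranges stored with the fit are the span of the calibration data
#' (pH) and the pressure regime the points were recorded in.
#'
#' @param points A data frame with columns `ph` and `i_ratio`; at least two
#'   distinct pH values.
#' @param pressure_range Lateral-pressure range (mN/m) the calibration was
#'   measured in; default `c(5, 8)`.
#' @return A [calibration_line()] carrying the fitted slope, intercept and
#'   residual sd.
#' @examples
#' fit_calibration(tibble::tibble(ph = c(6.5, 7.5), i_ratio = c(2.0, 2.6)))
#' @export
fit_calibration <- function(points, pressure_range = c(5, 8)) {
  points <- as_tibble(points)
  if (!all(c("ph", "i_ratio") %in% names(points))) {
    abort("`points` needs columns `ph` and `i_ratio`.")
  }
  if (length(unique(points$ph)) < 2L) {
    abort("Calibration needs at least two distinct pH values.")
  }
  fit <- lm(i_ratio ~ ph, data = points)
  cf <- coef(fit)
  if (!is.finite(cf[["ph"]]) || cf[["ph"]] == 0) {
    abort("Calibration fit is rank-deficient or has zero slope.")
  }
  dfres <- stats::df.residual(fit)
  cal <- calibration_line(
    slope = unname(cf[["ph"]]),
    intercept = unname(cf[["(Intercept)"]]),
    valid_ph_range = range(points$ph),
    valid_pressure_range = pressure_range,
    sigma = if (dfres > 0) sqrt(sum(stats::resid(fit)^2) / dfres) else 0
  )
  cal$fit <- fit
  cal$data <- points
  cal
}

#' @describeIn fit_calibration Slope/intercept rows with standard errors.
#' @param x A fitted `calibration_line`.
#' @param ... Unused.
#' @export
tidy.calibration_line <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = c("(Intercept)", "ph"),
                  estimate = c(x$intercept, x$slope)))
  }
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2])
}

#' @describeIn fit_calibration One-row summary with validity ranges.
#' @export
glance.calibration_line <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, sigma = x$sigma,
         ph_min = x$valid_ph_range[1], ph_max = x$valid_ph_range[2],
         pressure_min = x$valid_pressure_range[1],
         pressure_max = x$valid_pressure_range[2])
}

# ratio range implied by the calibration's valid pH range, expanded by the
# extrapolation margin (fraction of the ratio span)
calibration_ratio_range <- function(cal, margin) {
  r <- sort(cal$intercept + cal$slope * cal$valid_ph_range)
  r + c(-1, 1) * margin * diff(r)
}

#' Convert intensity ratios to pH
#'
#' Inverts the calibration line, `pH = (I_R - intercept) / slope`. Ratios
#' outside the calibrated range (plus a configurable extrapolation margin)
#' are flagged, not dropped: the calibration is only trustworthy inside the
#' regime it was measured in.
#'
#' @param cal A [calibration_line()].
#' @param i_ratio Numeric vector of intensity ratios.
#' @param margin Allowed extrapolation beyond the calibrated ratio range, as
#'   a fraction of that range (default 0.1).
#' @return A tibble with columns `i_ratio`, `ph`, `in_range` (logical). A
#'   warning is raised when any point falls outside the margin.
#' @examples
#' cal <- calibration_line(0.6, -1.9, c(6.5, 7.5))
#' ratio_to_ph(cal, 2.3)   # pH 7
#' @export
ratio_to_ph <- function(cal, i_ratio, margin = 0.1) {
  if (!inherits(cal, "calibration_line")) {
    abort("`cal` must be a `calibration_line`.")
  }
  rng <- calibration_ratio_range(cal, margin)
  in_range <- i_ratio >= rng[1] & i_ratio <= rng[2]
  if (any(!in_range)) {
    warn(sprintf(
      "%d of %d ratio values fall outside the calibrated range [%.3g, %.3g] (+%g%% margin).",
      sum(!in_range), length(i_ratio), rng[1], rng[2], 100 * margin
    ))
  }
  tibble(i_ratio = i_ratio, ph = (i_ratio - cal$intercept) / cal$slope,
         in_range = in_range)
}

#' Extract the pH pulse from a fluorescence trace
#'
#' Forms the intensity ratio `I_R = i535 / i605` sample-wise, optionally
#' smooths it with a centred moving average, converts it to interfacial pH
#' through the calibration, and reports the signed pH excursion (extremum
#' minus pre-arrival baseline). The sign of the Pearson correlation between
#' pH and lateral pressure over the pulse window classifies the coupling as
#' `"inverse"` (expansion raises pH) or `"direct"`.
#'
#' @param trace A [pulse_trace()] with channels `i535`, `i605` and `p1`.
#' @param cal A [calibration_line()].
#' @param smooth_window Odd moving-average window length in samples applied
#'   to the ratio before conversion; 1 (default) disables smoothing.
#' @param baseline_fraction Leading fraction of samples used as baseline.
#' @param margin Extrapolation margin passed to [ratio_to_ph()].
#' @return A list with `delta_ph` (signed pH excursion), `correlation_sign`
#'   (`"inverse"` or `"direct"`), `correlation` (the Pearson coefficient),
#'   `baseline_ph`, `t_peak`, `calibration_ok` (no out-of-range samples) and
#'   `ph_series`, a tibble of `time`, `ph`, `p1`, `in_range`.
#' @examples
#' cal <- calibration_line(0.6, -1.9, c(6.5, 7.7))
#' truth <- synthetic_truth(noise_sd = NULL)
#' tr <- make_fluorescence_trace(truth, cal, baseline_ph = 7, seed = 2)
#' extract_ph_pulse(tr, cal)$delta_ph
#' @export
extract_ph_pulse <- function(trace, cal, smooth_window = 1L,
                             baseline_fraction = 0.1, margin = 0.1) {
  if (!inherits(trace, "pulse_trace")) abort("`trace` must be a `pulse_trace`.")
  if (!all(c("i535", "i605", "p1") %in% names(trace))) {
    abort("`trace` needs channels `i535`, `i605` and `p1`.")
  }
  if (any(trace$i605 <= 0)) abort("`i605` must be strictly positive.")
  i_ratio <- moving_average(trace$i535 / trace$i605, smooth_window)

  conv <- ratio_to_ph(cal, i_ratio, margin = margin)
  ph <- conv$ph
  time <- trace$time
  p1 <- trace$p1

  bl <- channel_baseline(ph, baseline_fraction)
  dev <- ph - bl$mean
  i_peak <- which.max(abs(dev))
  delta_ph <- dev[i_peak]

  # pulse window: contiguous span where the excursion exceeds 20% of peak
  above <- which(abs(dev) >= 0.2 * abs(delta_ph))
  win <- seq(min(above), max(above))
  correlation <- if (sd(p1[win]) > 0 && sd(ph[win]) > 0) {
    cor(ph[win], p1[win])
  } else {
    NA_real_
  }

  list(
    delta_ph = delta_ph,
    correlation_sign = if (is.na(correlation)) NA_character_
                       else if (correlation < 0) "inverse" else "direct",
    correlation = correlation,
    baseline_ph = bl$mean,
    t_peak = time[i_peak],
    calibration_ok = all(conv$in_range),
    ph_series = tibble(time = time, ph = ph, p1 = p1,
                       in_range = conv$in_range)
  )
}
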