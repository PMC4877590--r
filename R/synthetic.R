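#' Ground truth for synthetic experiments
#'
#' Collects the parameters a synthetic experiment is generated from, so that
#' estimates recovered by the analysis chain can be compared against truth.
#' Defaults are the study conditions of the DMPS reference experiment this
#' package models: a 0.6 m/s pulse between sensors 15 cm apart, a 2.0 mN/m
#' expansion (negative) amplitude damped to 55% at the second sensor, a
#' +0.6 unit interfacial pH excursion and a +20 mV surface-potential pulse.
#'
#' @param transition_pressure Transition pressure in mN/m at the working pH.
#' @param pulse_velocity Pulse propagation velocity in m/s, > 0.
#' @param pulse_amplitude_s1 Signed pulse amplitude at sensor 1 in mN/m
#'   (negative = expansion).
#' @param damping_ratio Amplitude ratio sensor 2 / sensor 1, in `(0, 1]`.
#' @param delta_ph_interface Interfacial pH excursion during the pulse.
#' @param potential_amplitude Surface-potential pulse amplitude in mV, or
#'   `NULL` for no Kelvin-probe channel.
#' @param noise_sd Named numeric vector of per-channel additive Gaussian
#'   noise standard deviations; recognised names `p1`, `p2` (mN/m),
#'   `v_total` (mV), `i_ratio` (ratio units). Missing names default to 0.
#' @param rng_seed Integer seed recorded with the truth.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(transition_pressure = 21.9,
                            pulse_velocity = 0.6,
                            pulse_amplitude_s1 = -2.0,
                            damping_ratio = 0.55,
                            delta_ph_interface = 0.6,
                            potential_amplitude = 20,
                            noise_sd = c(p1 = 0.02, p2 = 0.02,
                                         v_total = 1, i_ratio = 0.01),
                            rng_seed = 1L) {
  if (pulse_velocity <= 0) abort("`pulse_velocity` must be > 0 (m/s).")
  if (damping_ratio <= 0 || damping_ratio > 1) {
    abort("`damping_ratio` must lie in (0, 1].")
  }
  full <- c(p1 = 0, p2 = 0, v_total = 0, i_ratio = 0)
  if (length(noise_sd)) {
    bad <- setdiff(names(noise_sd), names(full))
    if (length(bad) || is.null(names(noise_sd))) {
      abort("`noise_sd` must be named with a subset of p1, p2, v_total, i_ratio.")
    }
    full[names(noise_sd)] <- noise_sd
  }
  if (any(full < 0)) abort("`noise_sd` entries must be >= 0.")
  structure(
    list(
      transition_pressure = transition_pressure,
      pulse_velocity = pulse_velocity,
      pulse_amplitude_s1 = pulse_amplitude_s1,
      damping_ratio = damping_ratio,
      delta_ph_interface = delta_ph_interface,
      potential_amplitude = potential_amplitude,
      noise_sd = as.list(full),
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_truth"
  )
}

#' Equation-of-state parameters for synthetic isotherms
#'
#' A phenomenological two-branch equation of state for a titratable lipid
#' monolayer: linear liquid-expanded (LE) and liquid-condensed (LC) branches
#' blended by a logistic weight centred on the transition pressure,
#' `A(pi) = A_lc(pi) + (A_le(pi) - A_lc(pi)) * logistic((pi_T - pi) / w)`.
#' The form guarantees strictly decreasing `A(pi)` with a single
#' compressibility maximum at `pi_T` — the only structural features the
#' downstream analysis relies on. The transition pressure itself follows a
#' Boltzmann sigmoid in subphase pH whose default parameters are the DMPS
#' reference values (`A1 = 4.5`, `A2 = 24.4`, `x0 = 5.4`, `dx = 0.83`).
#'
#' @param A_lift Area in angstrom^2 where the LE branch reaches zero
#'   pressure (film lift-off).
#' @param le_slope,lc_slope Stiffness `dpi/dA` of the LE and LC branches in
#'   mN/m per angstrom^2; `lc_slope > le_slope > 0`.
#' @param plateau_area_drop Area lost across the LE/LC transition in
#'   angstrom^2, > 0.
#' @param plateau_width Width of the transition in mN/m, > 0.
#' @param transition_sigmoid Named list `A1`, `A2`, `x0`, `dx` mapping
#'   subphase pH to transition pressure (see [boltzmann_sigmoid()]).
#' @return An `eos_params` list.
#' @export
eos_params <- function(A_lift = 110,
                       le_slope = 0.7,
                       lc_slope = 4,
                       plateau_area_drop = 25,
                       plateau_width = 1.0,
                       transition_sigmoid = list(A1 = 4.5, A2 = 24.4,
                                                 x0 = 5.4, dx = 0.83)) {
  if (!(lc_slope > le_slope && le_slope > 0)) {
    abort("Branch stiffnesses must satisfy lc_slope > le_slope > 0.")
  }
  if (plateau_width <= 0) abort("`plateau_width` must be > 0 (mN/m).")
  if (plateau_area_drop <= 0) abort("`plateau_area_drop` must be > 0 (angstrom^2).")
  if (!all(c("A1", "A2", "x0", "dx") %in% names(transition_sigmoid))) {
    abort("`transition_sigmoid` needs A1, A2, x0, dx.")
  }
  structure(
    list(A_lift = A_lift, le_slope = le_slope, lc_slope = lc_slope,
         plateau_area_drop = plateau_area_drop, plateau_width = plateau_width,
         transition_sigmoid = transition_sigmoid),
    class = "eos_params"
  )
}

#' @describeIn eos_params Closed-form area per molecule at given pressures
#'   and transition pressure(s). `pi_T` defaults to the sigmoid value at
#'   pH 7.
#' @param eos An `eos_params` object.
#' @param pressure Lateral pressures in mN/m.
#' @param pi_T Transition pressure(s) in mN/m; scalar or one per pressure.
#' @export
eos_area <- function(eos, pressure, pi_T = NULL) {
  if (!inherits(eos, "eos_params")) abort("`eos` must be `eos_params`.")
  if (is.null(pi_T)) {
    s <- eos$transition_sigmoid
    pi_T <- boltzmann_sigmoid(7, s$A1, s$A2, s$x0, s$dx)
  }
  a_le <- eos$A_lift - pressure / eos$le_slope
  # LC branch anchored at the LE branch's area at pi_T, minus the plateau drop
  a_le_at_t <- eos$A_lift - pi_T / eos$le_slope
  a_lc <- a_le_at_t - eos$plateau_area_drop - (pressure - pi_T) / eos$lc_slope
  w <- stats::plogis((pi_T - pressure) / eos$plateau_width)
  a_lc + (a_le - a_lc) * w
}

# strict-monotone projection of an area sequence over increasing pressure
enforce_decreasing <- function(a, eps = 1e-9) {
  for (i in seq_along(a)[-1]) {
    if (a[i] >= a[i - 1]) a[i] <- a[i - 1] - eps
  }
  a
}

#' Generate a synthetic pressure-area isotherm
#'
#' Evaluates the [eos_params()] equation of state on a pressure grid, with
#' the transition pressure set by the EOS pH sigmoid at `subphase_ph`.
#' Noise perturbs the placement of the transition pressure (one Gaussian
#' draw per isotherm, mimicking run-to-run variability of the plateau)
#' rather than the areas directly, so generated isotherms remain strictly
#' monotone records at any noise level; the realised transition pressure is
#' recorded as the isotherm's ground truth.
#'
#' @param eos An [eos_params()] object.
#' @param subphase_ph Bulk subphase pH.
#' @param pressure_grid Strictly increasing pressures in mN/m, all >= 0.
#' @param noise_sd Standard deviation (mN/m) of the transition-pressure
#'   placement draw; 0 gives the exact closed form at the sigmoid value.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @param ... Passed to [isotherm()] (e.g. `molar_mass`).
#' @return An [isotherm()] whose compressibility maximum sits at the
#'   sigmoid's transition pressure for `subphase_ph`, within grid
#'   resolution.
#' @examples
#' iso <- make_isotherm(eos_params(), subphase_ph = 7,
#'                      pressure_grid = seq(0.5, 35, by = 0.25))
#' @export
make_isotherm <- function(eos, subphase_ph, pressure_grid,
                          noise_sd = 0, seed = NULL, ...) {
  if (!inherits(eos, "eos_params")) abort("`eos` must be `eos_params`.")
  if (length(pressure_grid) < 10L || any(diff(pressure_grid) <= 0)) {
    abort("`pressure_grid` must be strictly increasing with >= 10 points.")
  }
  if (any(pressure_grid < 0)) abort("`pressure_grid` must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")

  s <- eos$transition_sigmoid
  pi_T <- boltzmann_sigmoid(subphase_ph, s$A1, s$A2, s$x0, s$dx)

  if (noise_sd > 0) {
    if (is.null(seed)) abort("Supply an integer `seed` when `noise_sd > 0`.")
    pi_T <- pi_T + withr::with_seed(seed, rnorm(1, 0, noise_sd))
  }
  area <- enforce_decreasing(eos_area(eos, pressure_grid, pi_T))
  if (any(area <= 0)) {
    abort("EOS parameters yield non-positive areas on this grid.")
  }

  iso <- isotherm(tibble(area = area, pressure = pressure_grid),
                  subphase_ph = subphase_ph, ...)
  attr(iso, "true_transition_pressure") <- pi_T
  iso
}

#' Generate transition-pressure titration points
#'
#' Noiseless points lie exactly on the Boltzmann sigmoid; noise is additive
#' i.i.d. Gaussian on the transition pressure.
#'
#' @param sigmoid Named list `A1`, `A2`, `x0`, `dx` (see
#'   [boltzmann_sigmoid()]).
#' @param ph_grid pH values in `[0, 14]`; non-empty.
#' @param noise_sd Noise standard deviation in mN/m.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A [transition_curve()] tibble.
#' @examples
#' make_transition_points(list(A1 = 4.5, A2 = 24.4, x0 = 5.4, dx = 0.83),
#'                        seq(3, 9, 0.5), noise_sd = 0, seed = 1)
#' @export
make_transition_points <- function(sigmoid, ph_grid, noise_sd = 0, seed = NULL) {
  if (length(ph_grid) == 0L) abort("`ph_grid` must be non-empty.")
  if (any(ph_grid < 0) || any(ph_grid > 14)) abort("`ph_grid` must lie in [0, 14].")
  if (!all(c("A1", "A2", "x0", "dx") %in% names(sigmoid))) {
    abort("`sigmoid` needs A1, A2, x0, dx.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  pt <- boltzmann_sigmoid(ph_grid, sigmoid$A1, sigmoid$A2, sigmoid$x0, sigmoid$dx)
  if (noise_sd > 0) {
    if (is.null(seed)) abort("Supply an integer `seed` when `noise_sd > 0`.")
    pt <- pt + withr::with_seed(seed, rnorm(length(ph_grid), 0, noise_sd))
  }
  transition_curve(tibble(ph = ph_grid, transition_pressure = pt))
}

# unit-peak pulse waveform on a time axis, arriving/centred at t0
pulse_waveform <- function(time, t0, shape = c("exp_rise_decay", "gaussian"),
                           tau_rise = 0.05, tau_decay = 0.3, width = 0.1) {
  shape <- match.arg(shape)
  if (shape == "gaussian") {
    # onset at t0: centre the bell 3 widths later so the pre-arrival
    # baseline stays clean
    exp(-(time - t0 - 3 * width)^2 / (2 * width^2))
  } else {
    tt <- time - t0
    y <- ifelse(tt > 0, (1 - exp(-tt / tau_rise)) * exp(-tt / tau_decay), 0)
    t_peak <- tau_rise * log(1 + tau_decay / tau_rise)
    peak <- (1 - exp(-t_peak / tau_rise)) * exp(-t_peak / tau_decay)
    y / peak
  }
}

#' Generate two-sensor pulse traces
#'
#' Emulates a single acoustic pulse crossing the two pressure sensors: the
#' channel-2 waveform is the channel-1 waveform delayed by
#' `sensor_separation / pulse_velocity` and scaled by the damping ratio.
#' Delay and damping are imposed, not propagated — no wave equation is
#' solved. An optional Kelvin-probe channel carries a co-propagating
#' potential pulse of the truth's amplitude. Sensor quantisation
#' (0.01 mN/m, 5 mV), matching the instrument resolution the package
#' models, can be switched on for realism.
#'
#' @param truth A [synthetic_truth()].
#' @param sensor_separation Sensor spacing in m, > 0 (default 0.15 m).
#' @param sampling_rate Samples per second (default 10000, the instrument
#'   readout rate).
#' @param duration Trace length in s; must cover both arrivals.
#' @param pulse_shape `"exp_rise_decay"` (default; asymmetric rise and
#'   relaxation back to equilibrium) or `"gaussian"`.
#' @param seed Integer seed for the channel noise.
#' @param baseline_pressure Equilibrium lateral pressure in mN/m.
#' @param t_excite Arrival time of the pulse at sensor 1 in s.
#' @param tau_rise,tau_decay,width Waveform time constants in s.
#' @param quantize If `TRUE`, round pressures to 0.01 mN/m and potential to
#'   5 mV.
#' @return A [pulse_trace()] with channels `p1`, `p2` and, when the truth
#'   has a potential amplitude, `v_total`.
#' @examples
#' tr <- make_pulse_traces(synthetic_truth(noise_sd = NULL), seed = 7)
#' pulse_features(tr)$velocity
#' @export
make_pulse_traces <- function(truth,
                              sensor_separation = 0.15,
                              sampling_rate = 10000,
                              duration = 2,
                              pulse_shape = c("exp_rise_decay", "gaussian"),
                              seed = truth$rng_seed,
                              baseline_pressure = 8,
                              t_excite = 0.3,
                              tau_rise = 0.05, tau_decay = 0.3, width = 0.1,
                              quantize = FALSE) {
  if (!inherits(truth, "synthetic_truth")) {
    abort("`truth` must be a `synthetic_truth`.")
  }
  pulse_shape <- match.arg(pulse_shape)
  if (sensor_separation <= 0) abort("`sensor_separation` must be > 0 (m).")
  if (sampling_rate <= 0) abort("`sampling_rate` must be > 0 (Hz).")
  delay <- sensor_separation / truth$pulse_velocity
  tail_time <- if (pulse_shape == "gaussian") 6 * width else 3 * tau_decay
  if (t_excite + delay + tail_time >= duration) {
    abort(sprintf(
      "Duration %g s does not cover the second arrival (delay %g s) and relaxation.",
      duration, delay
    ))
  }

  time <- seq(0, duration, by = 1 / sampling_rate)
  s1 <- pulse_waveform(time, t_excite, pulse_shape, tau_rise, tau_decay, width)
  s2 <- pulse_waveform(time, t_excite + delay, pulse_shape, tau_rise, tau_decay, width)

  amp <- truth$pulse_amplitude_s1
  nsd <- truth$noise_sd
  noise <- withr::with_seed(seed, list(
    p1 = rnorm(length(time), 0, nsd$p1),
    p2 = rnorm(length(time), 0, nsd$p2),
    v  = rnorm(length(time), 0, nsd$v_total)
  ))

  p1 <- baseline_pressure + amp * s1 + noise$p1
  p2 <- baseline_pressure + truth$damping_ratio * amp * s2 + noise$p2
  dat <- tibble(time = time, p1 = p1, p2 = p2)
  if (!is.null(truth$potential_amplitude)) {
    dat$v_total <- truth$potential_amplitude * s1 + noise$v
  }
  if (quantize) {
    dat$p1 <- round(dat$p1 / 0.01) * 0.01
    dat$p2 <- round(dat$p2 / 0.01) * 0.01
    if (!is.null(dat$v_total)) dat$v_total <- round(dat$v_total / 5) * 5
  }
  pulse_trace(dat, sampling_rate = sampling_rate,
              sensor_separation = sensor_separation)
}

#' Generate a ratiometric fluorescence trace with a pH pulse
#'
#' Emulates the optical record of a propagating pH pulse: the interfacial pH
#' follows the pulse waveform from `baseline_ph` with excursion
#' `truth$delta_ph_interface`, the intensity ratio `I_535/I_605` follows the
#' calibration line, and the two raw intensity channels are a positive pair
#' realising that ratio (constant `i605`). A pressure pulse of the truth's
#' (negative, expansion) amplitude is written to `p1`/`p2` so that
#' pressure-pH correlation can be assessed downstream.
#'
#' @param truth A [synthetic_truth()].
#' @param calibration A [calibration_line()] (or [fit_calibration()]
#'   result).
#' @param baseline_ph Interfacial pH before the pulse; the full excursion
#'   must stay inside the calibration validity range.
#' @param sampling_rate Samples per second.
#' @param seed Integer seed.
#' @param duration Trace length in s.
#' @param i605_level Constant level of the reference intensity channel.
#' @inheritParams make_pulse_traces
#' @return A [pulse_trace()] with channels `p1`, `p2`, `i535`, `i605`.
#' @export
make_fluorescence_trace <- function(truth, calibration,
                                    baseline_ph = 7.0,
                                    sampling_rate = 1000,
                                    seed = truth$rng_seed,
                                    duration = 2,
                                    pulse_shape = c("exp_rise_decay", "gaussian"),
                                    sensor_separation = 0.15,
                                    baseline_pressure = 6.5,
                                    t_excite = 0.3,
                                    tau_rise = 0.05, tau_decay = 0.3,
                                    width = 0.1,
                                    i605_level = 1.0) {
  if (!inherits(truth, "synthetic_truth")) {
    abort("`truth` must be a `synthetic_truth`.")
  }
  if (!inherits(calibration, "calibration_line")) {
    abort("`calibration` must be a `calibration_line`.")
  }
  pulse_shape <- match.arg(pulse_shape)
  rng <- calibration$valid_ph_range
  ph_extreme <- baseline_ph + truth$delta_ph_interface
  if (baseline_ph < rng[1] || baseline_ph > rng[2] ||
      ph_extreme < rng[1] || ph_extreme > rng[2]) {
    abort(sprintf(
      "pH excursion [%g, %g] leaves the calibration validity range [%g, %g].",
      min(baseline_ph, ph_extreme), max(baseline_ph, ph_extreme), rng[1], rng[2]
    ))
  }

  time <- seq(0, duration, by = 1 / sampling_rate)
  s <- pulse_waveform(time, t_excite, pulse_shape, tau_rise, tau_decay, width)
  s2 <- pulse_waveform(time, t_excite + sensor_separation / truth$pulse_velocity,
                       pulse_shape, tau_rise, tau_decay, width)

  ph_t <- baseline_ph + truth$delta_ph_interface * s
  i_ratio <- calibration$intercept + calibration$slope * ph_t

  nsd <- truth$noise_sd
  noise <- withr::with_seed(seed, list(
    r  = rnorm(length(time), 0, nsd$i_ratio),
    p1 = rnorm(length(time), 0, nsd$p1),
    p2 = rnorm(length(time), 0, nsd$p2)
  ))

  dat <- tibble(
    time = time,
    p1 = baseline_pressure + truth$pulse_amplitude_s1 * s + noise$p1,
    p2 = baseline_pressure +
      truth$damping_ratio * truth$pulse_amplitude_s1 * s2 + noise$p2,
    i535 = (i_ratio + noise$r) * i605_level,
    i605 = i605_level
  )
  pulse_trace(dat, sampling_rate = sampling_rate,
              sensor_separation = sensor_separation)
}

#' Generate and write a complete synthetic experiment bundle
#'
#' One call produces every input the analysis chain consumes — a set of
#' isotherms across subphase pH, a transition-pressure titration curve,
#' two-sensor pressure traces, calibration points and a fluorescence trace —
#' and writes them as CSV files in the package's external dialects, plus the
#' generating truth as a JSON sidecar. Deterministic under a fixed seed.
#'
#' @param outdir Directory to write into (created if needed).
#' @param seed Integer master seed; per-file seeds are derived from it.
#' @param config Optional named list overriding bundle parameters:
#'   `isotherm_ph` (vector of subphase pH values), `pressure_grid`,
#'   `titration_ph`, `titration_noise_sd`, `isotherm_noise_sd`, plus any
#'   [synthetic_truth()] argument under `truth`.
#' @return Invisibly, a list with the generated objects and the written file
#'   paths.
#' @examples
#' \donttest{
#' b <- make_experiment_bundle(tempfile("bundle"), seed = 1)
#' names(b$paths)
#' }
#' @export
make_experiment_bundle <- function(outdir, seed = 1L, config = list()) {
  defaults <- list(
    isotherm_ph = c(3, 5, 5.4, 7, 9),
    pressure_grid = seq(0.5, 35, by = 0.25),
    titration_ph = seq(3, 9, by = 0.5),
    titration_noise_sd = 0.2,
    isotherm_noise_sd = 0.05,
    calibration_ph = c(6.5, 7.0, 7.5),
    truth = list()
  )
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) abort(paste0("Unknown bundle config key(s): ", toString(bad)))
  cfg <- utils::modifyList(defaults, config)

  truth <- do.call(synthetic_truth, cfg$truth)
  truth$rng_seed <- as.integer(seed)
  eos <- eos_params()
  sig <- eos$transition_sigmoid

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  isos <- purrr::imap(stats::setNames(cfg$isotherm_ph, paste0("ph", cfg$isotherm_ph)),
    function(ph, nm) {
      make_isotherm(eos, ph, cfg$pressure_grid,
                    noise_sd = cfg$isotherm_noise_sd,
                    seed = seed + 101L + round(100 * ph))
    })
  for (nm in names(isos)) {
    paths[[paste0("isotherm_", nm)]] <-
      write_isotherm(isos[[nm]], file.path(outdir, paste0("isotherm_", nm, ".csv")))
  }

  titration <- make_transition_points(sig, cfg$titration_ph,
                                      noise_sd = cfg$titration_noise_sd,
                                      seed = seed + 7L)
  paths$titration <- write_transition_curve(titration,
                                            file.path(outdir, "titration.csv"))

  # calibration points span pH 6.5-7.5; the stored line allows the 10%
  # extrapolation the converter tolerates so the 0.6-unit pulse stays legal
  cal_line <- calibration_line(slope = 0.6, intercept = -1.9,
                               valid_ph_range = c(6.4, 7.6),
                               valid_pressure_range = c(5, 8))
  cal_pts <- tibble(
    ph = cfg$calibration_ph,
    i_ratio = cal_line$intercept + cal_line$slope * cfg$calibration_ph +
      withr::with_seed(seed + 11L,
                       rnorm(length(cfg$calibration_ph), 0, 0.02))
  )
  paths$calibration <- readr_write(cal_pts, file.path(outdir, "calibration.csv"))

  pressure_trace <- make_pulse_traces(truth, seed = seed + 23L)
  paths$pressure_trace <- write_pulse_trace(pressure_trace,
                                            file.path(outdir, "pressure_trace.csv"))

  fluo_trace <- make_fluorescence_trace(truth, cal_line, seed = seed + 31L)
  paths$fluorescence_trace <- write_pulse_trace(fluo_trace,
                                                file.path(outdir, "fluorescence_trace.csv"))

  truth_out <- truth
  class(truth_out) <- NULL
  paths$truth <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth_out, paths$truth, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  invisible(list(
    isotherms = isos, titration = titration, calibration_points = cal_pts,
    calibration = cal_line, pressure_trace = pressure_trace,
    fluorescence_trace = fluo_trace, truth = truth, paths = paths
  ))
}
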