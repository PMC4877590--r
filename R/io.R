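# All files are comma-separated with a header row, '.' decimal, UTF-8.
# Canonical units (angstrom^2, mN/m, mV, s, K) are restored at this boundary.

readr_write <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

read_csv_quiet <- function(path, required) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Missing column(s) in ", basename(path), ": ",
                 toString(missing)))
  }
  df
}

#' Read and write pressure-area isotherms
#'
#' The isotherm dialect has columns `area_A2` (angstrom^2 per molecule; or
#' `area_nm2` with `area_unit = "nm2"`, converted on read) and
#' `pressure_mN_m`. Rows may be in any order; the result is canonically
#' sorted and validated by [isotherm()].
#'
#' @param path CSV file path.
#' @param area_unit Unit of the area column: `"A2"` (default) or `"nm2"`.
#' @param ... Metadata passed to [isotherm()] (`temperature`,
#'   `subphase_ph`, `lipid_label`, `molar_mass`).
#' @return An [isotherm()].
#' @export
read_isotherm <- function(path, area_unit = c("A2", "nm2"), ...) {
  area_unit <- match.arg(area_unit)
  col <- if (area_unit == "A2") "area_A2" else "area_nm2"
  df <- read_csv_quiet(path, c(col, "pressure_mN_m"))
  area <- df[[col]] * if (area_unit == "nm2") 100 else 1
  isotherm(tibble(area = area, pressure = df$pressure_mN_m), ...)
}

#' @describeIn read_isotherm Write an isotherm in the same dialect; returns
#'   the path invisibly.
#' @param iso An [isotherm()].
#' @export
write_isotherm <- function(iso, path) {
  if (!inherits(iso, "isotherm")) abort("`iso` must be an `isotherm`.")
  readr_write(tibble(area_A2 = iso$area, pressure_mN_m = iso$pressure), path)
}

#' Read and write transition-pressure titration curves
#'
#' Dialect: columns `ph` and `transition_pressure_mN_m`.
#'
#' @param path CSV file path.
#' @return A [transition_curve()].
#' @export
read_transition_curve <- function(path) {
  df <- read_csv_quiet(path, c("ph", "transition_pressure_mN_m"))
  transition_curve(tibble(ph = df$ph,
                          transition_pressure = df$transition_pressure_mN_m))
}

#' @describeIn read_transition_curve Write a titration curve; returns the
#'   path invisibly.
#' @param curve A [transition_curve()].
#' @export
write_transition_curve <- function(curve, path) {
  readr_write(tibble(ph = curve$ph,
                     transition_pressure_mN_m = curve$transition_pressure),
              path)
}

#' Read and write multichannel pulse traces
#'
#' Dialect: columns `time_s`, `p1_mN_m`, `p2_mN_m` and optionally
#' `v_total_mV`, `i535`, `i605`.
#'
#' @param path CSV file path.
#' @param sensor_separation Sensor spacing in m (not stored in the file).
#' @param excitation_distance Optional excitation distance in m.
#' @return A [pulse_trace()].
#' @export
read_pulse_trace <- function(path, sensor_separation = 0.15,
                             excitation_distance = NULL) {
  df <- read_csv_quiet(path, c("time_s", "p1_mN_m", "p2_mN_m"))
  dat <- tibble(time = df$time_s, p1 = df$p1_mN_m, p2 = df$p2_mN_m)
  if ("v_total_mV" %in% names(df)) dat$v_total <- df$v_total_mV
  if (all(c("i535", "i605") %in% names(df))) {
    dat$i535 <- df$i535
    dat$i605 <- df$i605
  }
  pulse_trace(dat, sensor_separation = sensor_separation,
              excitation_distance = excitation_distance)
}

#' @describeIn read_pulse_trace Write a pulse trace; returns the path
#'   invisibly.
#' @param trace A [pulse_trace()].
#' @export
write_pulse_trace <- function(trace, path) {
  if (!inherits(trace, "pulse_trace")) abort("`trace` must be a `pulse_trace`.")
  out <- tibble(time_s = trace$time, p1_mN_m = trace$p1, p2_mN_m = trace$p2)
  if ("v_total" %in% names(trace)) out$v_total_mV <- trace$v_total
  if ("i535" %in% names(trace)) {
    out$i535 <- trace$i535
    out$i605 <- trace$i605
  }
  readr_write(out, path)
}

#' Read calibration points
#'
#' Dialect: columns `ph` and `i_ratio`.
#'
#' @param path CSV file path.
#' @return A tibble with columns `ph`, `i_ratio`, ready for
#'   [fit_calibration()].
#' @export
read_calibration_points <- function(path) {
  read_csv_quiet(path, c("ph", "i_ratio"))[c("ph", "i_ratio")]
}

#' Read a synthetic-truth sidecar
#'
#' @param path JSON file written by [make_experiment_bundle()].
#' @return A [synthetic_truth()].
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(
    transition_pressure = x$transition_pressure,
    pulse_velocity = x$pulse_velocity,
    pulse_amplitude_s1 = x$pulse_amplitude_s1,
    damping_ratio = x$damping_ratio,
    delta_ph_interface = x$delta_ph_interface,
    potential_amplitude = x$potential_amplitude,
    noise_sd = unlist(x$noise_sd),
    rng_seed = x$rng_seed
  )
}
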