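#' Construct and validate a pressure-area isotherm
#'
#' A quasi-static Langmuir isotherm: lateral pressure `pi` (mN/m) against
#' area per molecule `A` (angstrom^2) at fixed temperature and subphase pH.
#' Records are canonically sorted by increasing pressure; area must then be
#' non-increasing (compression reduces area). Violations of monotonicity
#' larger than 0.5% of the area range are rejected as corrupt input.
#'
#' @param data A data frame with columns `area` (angstrom^2) and `pressure`
#'   (mN/m); at least 10 rows.
#' @param temperature Temperature in K.
#' @param subphase_ph Bulk pH of the subphase.
#' @param lipid_label Free-text lipid identifier.
#' @param molar_mass Molar mass of the lipid in g/mol (needed for velocity
#'   profiles). Default 679.9 g/mol for DMPS; a configuration default that
#'   users should check against their lipid's data sheet.
#' @return An `isotherm` tibble with attributes `temperature`,
#'   `subphase_ph`, `lipid_label`, `molar_mass`.
#' @examples
#' iso <- isotherm(
#'   tibble::tibble(pressure = 0:14, area = 100 - 2 * (0:14)),
#'   subphase_ph = 7
#' )
#' @export
isotherm <- function(data, temperature = 298.15, subphase_ph = 7.0,
                     lipid_label = "DMPS", molar_mass = 679.9) {
  data <- as_tibble(data)
  if (!all(c("area", "pressure") %in% names(data))) {
    abort("`data` needs columns `area` and `pressure`.")
  }
  if (nrow(data) < 10L) abort("An isotherm needs at least 10 records.")
  if (any(!is.finite(data$area)) || any(!is.finite(data$pressure))) {
    abort("Isotherm records must be finite.")
  }
  if (any(data$pressure < 0)) abort("`pressure` must be >= 0 (mN/m).")
  if (any(data$area <= 0)) abort("`area` must be > 0 (angstrom^2).")

  out <- arrange(data[c("area", "pressure")], .data$pressure, dplyr::desc(.data$area))
  rises <- diff(out$area)
  tol <- 0.005 * diff(range(out$area))
  if (any(rises > tol)) {
    abort(paste0(
      "Area increases with pressure beyond tolerance (max rise ",
      format(max(rises), digits = 3), " angstrom^2): not a valid isotherm."
    ))
  }

  attr(out, "temperature") <- temperature
  attr(out, "subphase_ph") <- subphase_ph
  attr(out, "lipid_label") <- lipid_label
  attr(out, "molar_mass") <- molar_mass
  class(out) <- c("isotherm", class(out))
  out
}

# monotone table lookup: Hyman-filtered spline when the data allow it,
# linear interpolation otherwise (and always for < 4 points)
monotone_interp <- function(x, y) {
  ok <- length(x) >= 4 &&
    (all(diff(y) <= 0) || all(diff(y) >= 0)) &&
    all(diff(x) > 0)
  if (ok && length(unique(y)) > 1) {
    tryCatch(
      splinefun(x, y, method = "hyman"),
      error = function(e) approxfun(x, y, rule = 1)
    )
  } else {
    approxfun(x, y, rule = 1, ties = mean)
  }
}

#' Isothermal compressibility profile of an isotherm
#'
#' The lateral isothermal compressibility
#' `kappa_T(pi) = -(1/A) (dA/dpi)_T` in (mN/m)^-1, evaluated on the interior
#' of the isotherm's pressure grid. The derivative is taken analytically
#' from a smoothing spline fitted to `A(pi)` (finite differences on noisy
#' records produce spurious negative compressibilities). `kappa_T` is
#' maximal at the liquid-expanded / liquid-condensed transition and is the
#' working approximation for the adiabatic compressibility that sets the
#' sound velocity.
#'
#' @param iso An [isotherm()].
#' @param smoothing Smoothing control: `NULL` (default) selects the
#'   smoothing parameter by generalized cross-validation and, because a
#'   valid monotone isotherm must have a one-signed derivative, escalates
#'   it stepwise if the interior derivative still changes sign; `0` uses an
#'   interpolating cubic spline (no smoothing, for clean synthetic or
#'   analytic isotherms); a number in `(0, 1.5]` is passed as `spar` to
#'   [stats::smooth.spline()] verbatim.
#' @return A `compressibility_profile` tibble with columns `pressure`
#'   (mN/m) and `kappa_T` ((mN/m)^-1), attribute `smoothing`.
#' @examples
#' iso <- isotherm(tibble::tibble(pressure = seq(0, 30, 0.5),
#'                                area = 100 * exp(-0.02 * seq(0, 30, 0.5))))
#' kp <- compressibility_profile(iso, smoothing = 0)
#' range(kp$kappa_T)   # constant 0.02 for an exponential isotherm
#' @export
compressibility_profile <- function(iso, smoothing = NULL) {
  if (!inherits(iso, "isotherm")) abort("`iso` must be an `isotherm`.")
  p <- iso$pressure
  a <- iso$area
  keep <- !duplicated(p)
  p <- p[keep]; a <- a[keep]
  if (length(p) < 4L) abort("Too few distinct pressures to differentiate.")

  # boundary derivatives of a spline are unreliable; keep the interior
  idx <- seq(2L, length(p) - 1L)
  eval_spline <- function(spar) {
    fit <- if (is.null(spar)) smooth.spline(p, a, cv = FALSE)
           else smooth.spline(p, a, spar = spar)
    list(a_hat = predict(fit, p)$y, dA = predict(fit, p, deriv = 1)$y,
         spar = fit$spar)
  }

  if (!is.null(smoothing) && identical(as.numeric(smoothing), 0)) {
    sf <- splinefun(p, a, method = "fmm")
    res <- list(a_hat = a, dA = sf(p, deriv = 1), spar = 0)
    used <- 0
  } else if (!is.null(smoothing)) {
    res <- eval_spline(smoothing)
    used <- smoothing
  } else {
    # GCV start; a monotone record must have a one-signed derivative, so
    # escalate the smoothing until the interior derivative is negative
    res <- eval_spline(NULL)
    used <- res$spar
    while (any(res$dA[idx] >= 0) && used < 1.5) {
      used <- used + 0.1
      res <- eval_spline(used)
    }
  }

  kappa <- -res$dA[idx] / res$a_hat[idx]
  if (any(!is.finite(kappa)) || any(kappa <= 0)) {
    abort(paste0(
      "Non-positive compressibility after smoothing: the isotherm is not ",
      "strictly decreasing where differentiated (corrupt input or oversmoothing)."
    ))
  }

  out <- tibble(pressure = p[idx], kappa_T = kappa)
  attr(out, "smoothing") <- used
  attr(out, "isotherm") <- iso
  class(out) <- c("compressibility_profile", class(out))
  out
}

#' Sound-velocity profile from compressibility and lateral density
#'
#' In the linear acoustic regime the in-plane sound velocity is
#' `c = 1 / sqrt(rho_0 kappa)`, with `rho_0` the lateral mass density and
#' `kappa` the (adiabatic, here approximated isothermal) compressibility.
#' The lateral density is `rho_0(pi) = M / (N_A A(pi))` times an effective
#' density factor: with factor 1 only the lipid mass is counted, which
#' yields velocities far above the ~1 m/s measured for monolayer pulses —
#' entrained subphase mass is not modelled — so the profile is meaningful
#' for its shape (the minimum at the transition), not its absolute scale.
#'
#' @param kprof A [compressibility_profile()].
#' @param iso The source [isotherm()]; defaults to the one the profile was
#'   computed from.
#' @param effective_density_factor Dimensionless multiplier on the lipid
#'   areal density (default 1, `lipid_only`).
#' @return A `velocity_profile` tibble with columns `pressure` (mN/m) and
#'   `velocity` (m/s), attribute `effective_density_factor`.
#' @examples
#' iso <- isotherm(tibble::tibble(pressure = seq(0, 30, 0.5),
#'                                area = 100 * exp(-0.02 * seq(0, 30, 0.5))))
#' vp <- sound_velocity_profile(compressibility_profile(iso, smoothing = 0))
#' @export
sound_velocity_profile <- function(kprof, iso = attr(kprof, "isotherm"),
                                   effective_density_factor = 1) {
  if (!inherits(kprof, "compressibility_profile")) {
    abort("`kprof` must be a `compressibility_profile`.")
  }
  if (is.null(iso)) abort("Supply the source `isotherm` via `iso`.")
  M <- attr(iso, "molar_mass")
  if (is.null(M) || !is.finite(M) || M <= 0) {
    abort("The isotherm needs a positive `molar_mass` (g/mol).")
  }
  if (effective_density_factor <= 0) {
    abort("`effective_density_factor` must be > 0.")
  }

  a_of_p <- monotone_interp(iso$pressure[!duplicated(iso$pressure)],
                            iso$area[!duplicated(iso$pressure)])
  area <- a_of_p(kprof$pressure)                       # angstrom^2
  cst <- physical_constants()
  rho <- effective_density_factor * (M * 1e-3) / (cst$N_A * area * A2_to_m2)  # kg/m^2
  kappa_si <- kprof$kappa_T / mN_per_m_to_N_per_m      # (N/m)^-1
  velocity <- 1 / sqrt(rho * kappa_si)                 # m/s

  out <- tibble(pressure = kprof$pressure, velocity = velocity)
  attr(out, "effective_density_factor") <- effective_density_factor
  class(out) <- c("velocity_profile", class(out))
  out
}

#' Transition pressure from the compressibility maximum
#'
#' The first-order liquid-expanded / liquid-condensed transition shows up as
#' the global maximum of `kappa_T(pi)`; its pressure is the transition
#' pressure `pi_T`. A maximum sitting on the profile boundary signals a
#' truncated isotherm and is an error; exact ties are broken toward the
#' lower pressure.
#'
#' @param kprof A [compressibility_profile()].
#' @return Transition pressure in mN/m.
#' @export
find_transition_pressure <- function(kprof) {
  if (!inherits(kprof, "compressibility_profile")) {
    abort("`kprof` must be a `compressibility_profile`.")
  }
  i <- which.max(kprof$kappa_T)   # first index on ties -> lower pressure
  if (i == 1L || i == nrow(kprof)) {
    abort(paste0(
      "Compressibility maximum lies on the grid boundary: the isotherm does ",
      "not bracket the phase transition."
    ))
  }
  kprof$pressure[i]
}

#' Map a pressure excursion to an area excursion
#'
#' Reads the quasi-static area change corresponding to a pressure pulse off
#' the isotherm by monotone interpolation: an expansion pulse
#' (`delta_p < 0`) increases the area.
#'
#' @param iso An [isotherm()].
#' @param p_start Baseline pressure in mN/m.
#' @param delta_p Signed pressure excursion in mN/m.
#' @return A tibble with one row: `p_start`, `p_end`, `area_start`,
#'   `area_end` (angstrom^2).
#' @examples
#' iso <- isotherm(tibble::tibble(pressure = 0:19, area = 100 - 2 * (0:19)))
#' pressure_to_area(iso, p_start = 10, delta_p = -2.4)
#' @export
pressure_to_area <- function(iso, p_start, delta_p) {
  if (!inherits(iso, "isotherm")) abort("`iso` must be an `isotherm`.")
  p_end <- p_start + delta_p
  rng <- range(iso$pressure)
  if (p_start < rng[1] || p_start > rng[2] || p_end < rng[1] || p_end > rng[2]) {
    abort(sprintf(
      "Pressures [%g, %g] fall outside the isotherm range [%g, %g] mN/m.",
      min(p_start, p_end), max(p_start, p_end), rng[1], rng[2]
    ))
  }
  keep <- !duplicated(iso$pressure)
  a_of_p <- monotone_interp(iso$pressure[keep], iso$area[keep])
  tibble(
    p_start = p_start, p_end = p_end,
    area_start = a_of_p(p_start), area_end = a_of_p(p_end)
  )
}

#' Compose surface potential against pressure
#'
#' Concatenates an isothermal `A(pi)` record with an isothermal surface
#' potential record `V_total(A)` into the relation `V_total(pi)` on the
#' overlap of their ranges, using monotone interpolation for both steps.
#' This quasi-static relation predicts the electrical pulse that accompanies
#' a given pressure pulse.
#'
#' @param iso An [isotherm()].
#' @param vcurve A data frame with columns `area` (angstrom^2) and `v_total`
#'   (mV), monotone in area.
#' @return A `potential_pressure_map`: a tibble with columns `pressure`
#'   (mN/m) and `v_total` (mV) on the overlap grid, carrying an interpolator
#'   used by [predict.potential_pressure_map()] and
#'   [quasi_static_potential_prediction()].
#' @export
potential_pressure_map <- function(iso, vcurve) {
  if (!inherits(iso, "isotherm")) abort("`iso` must be an `isotherm`.")
  vcurve <- as_tibble(vcurve)
  if (!all(c("area", "v_total") %in% names(vcurve))) {
    abort("`vcurve` needs columns `area` and `v_total`.")
  }
  vcurve <- arrange(vcurve, .data$area)

  keep <- !duplicated(iso$pressure)
  p <- iso$pressure[keep]
  a <- iso$area[keep]
  inside <- a >= min(vcurve$area) & a <= max(vcurve$area)
  if (sum(inside) < 2L) {
    abort("Isotherm and potential curve have (nearly) disjoint area ranges.")
  }

  a_of_p <- monotone_interp(p, a)
  v_of_a <- monotone_interp(vcurve$area, vcurve$v_total)
  fn <- function(pressure) v_of_a(a_of_p(pressure))

  grid <- p[inside]
  out <- tibble(pressure = grid, v_total = fn(grid))
  attr(out, "fn") <- fn
  attr(out, "domain") <- range(grid)
  class(out) <- c("potential_pressure_map", class(out))
  out
}

#' @describeIn potential_pressure_map Evaluate the map at new pressures.
#' @param object A `potential_pressure_map`.
#' @param pressure Pressures in mN/m, inside the map's domain.
#' @param ... Unused.
#' @export
predict.potential_pressure_map <- function(object, pressure, ...) {
  dom <- attr(object, "domain")
  if (any(pressure < dom[1]) || any(pressure > dom[2])) {
    abort(sprintf("Pressure outside the map domain [%g, %g] mN/m.",
                  dom[1], dom[2]))
  }
  attr(object, "fn")(pressure)
}
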