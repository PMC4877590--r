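#' Electrolyte environment of the subphase
#'
#' Describes the aqueous subphase under the monolayer as an effective 1:1
#' electrolyte. The default ionic strength of 0.11 mol/L corresponds to
#' 100 mM NaCl plus 10 mM phosphate buffer counted as a 1:1 contribution;
#' with the default temperature and permittivity this is the setting that
#' reproduces the reference head-group potentials for DMPS (see the package
#' vignette).
#'
#' @param ionic_strength Effective 1:1 ionic strength in mol/L. Must be > 0.
#' @param temperature Absolute temperature in K. Default 298.15 K (25 degC).
#' @param relative_permittivity Relative permittivity of the subphase
#'   (dimensionless, in `[1, 100]`). Default 78.5 (water at 25 degC).
#' @param bulk_ph Bulk pH of the subphase.
#' @return An object of class `electrolyte`: a named list with the validated
#'   fields above.
#' @examples
#' electrolyte()
#' electrolyte(ionic_strength = 0.01, temperature = 293.15)
#' @export
electrolyte <- function(ionic_strength = 0.11,
                        temperature = 298.15,
                        relative_permittivity = 78.5,
                        bulk_ph = 7.0) {
  if (!is.numeric(ionic_strength) || length(ionic_strength) != 1L ||
      !is.finite(ionic_strength) || ionic_strength <= 0) {
    abort("`ionic_strength` must be a single positive number (mol/L).")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be positive (K).")
  }
  if (relative_permittivity < 1 || relative_permittivity > 100) {
    abort("`relative_permittivity` must lie in [1, 100].")
  }
  if (bulk_ph < 0 || bulk_ph > 14) {
    abort("`bulk_ph` must lie in [0, 14].")
  }
  structure(
    list(
      ionic_strength = ionic_strength,
      temperature = temperature,
      relative_permittivity = relative_permittivity,
      bulk_ph = bulk_ph
    ),
    class = "electrolyte"
  )
}

#' @export
print.electrolyte <- function(x, ...) {
  cat(sprintf(
    "<electrolyte> I = %g mol/L (1:1 effective), T = %g K, eps_r = %g, bulk pH = %g\n",
    x$ionic_strength, x$temperature, x$relative_permittivity, x$bulk_ph
  ))
  invisible(x)
}

stopifnot_electrolyte <- function(env) {
  if (!inherits(env, "electrolyte")) {
    abort("`env` must be created with `electrolyte()`.")
  }
  invisible(env)
}

#' Surface charge density of a partially dissociated monolayer
#'
#' Only the titratable serine carboxyl carries net charge (the phosphate and
#' amino charges of the PS head group compensate), so the surface charge
#' density is `sigma = -alpha * e / area`: negative for a deprotonated
#' carboxyl, zero when fully protonated.
#'
#' @param area Area per molecule in angstrom^2. Must be > 0.
#' @param alpha Dissociation degree in `[0, 1]`.
#' @return Surface charge density in C/m^2 (signed, <= 0). Vectorised over
#'   `area` and `alpha`.
#' @examples
#' surface_charge_density(75, 0.88)
#' @export
surface_charge_density <- function(area, alpha) {
  check_area_alpha(area, alpha)
  cst <- physical_constants()
  -alpha * cst$e / (area * A2_to_m2)
}

check_area_alpha <- function(area, alpha) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    abort("`area` must be positive and finite (angstrom^2).")
  }
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    abort("`alpha` must lie in [0, 1].")
  }
  invisible(NULL)
}

# ionic number density (1/m^3) of a 1:1 electrolyte at molar strength I
ionic_number_density <- function(ionic_strength) {
  physical_constants()$N_A * ionic_strength * 1e3
}

#' Gouy-Chapman head-group potential
#'
#' Diffuse-double-layer potential of a uniformly charged plane in a 1:1
#' electrolyte,
#' `psi = (2 kT / e) * asinh(sigma / sqrt(8 eps0 eps_r kT n))`,
#' with `n` the ionic number density. This is the exact inverse of the
#' Grahame charge-potential relation. The charge density comes from
#' [surface_charge_density()], so a deprotonated carboxyl gives a negative
#' potential whose magnitude grows with dissociation and shrinks with area
#' and ionic strength.
#'
#' @inheritParams surface_charge_density
#' @param env An [electrolyte()] object.
#' @return Head-group potential psi in mV (signed). Vectorised over `area`
#'   and `alpha`.
#' @examples
#' gouy_chapman_potential(75, 0.88, electrolyte())   # about -117 mV
#' gouy_chapman_potential(82, 0.88, electrolyte())   # about -113 mV
#' @export
gouy_chapman_potential <- function(area, alpha, env = electrolyte()) {
  stopifnot_electrolyte(env)
  sigma <- surface_charge_density(area, alpha)
  cst <- physical_constants()
  kT <- cst$k_B * env$temperature
  n <- ionic_number_density(env$ionic_strength)
  denom <- sqrt(8 * cst$epsilon_0 * env$relative_permittivity * kT * n)
  psi_volt <- (2 * kT / cst$e) * asinh(sigma / denom)
  psi_volt / mV_to_V
}

#' Debye screening length
#'
#' `lambda_D = sqrt(eps0 eps_r kT / (2 n e^2))` for a 1:1 electrolyte;
#' useful for the small-charge (Debye-Hueckel) limit `psi = sigma lambda_D /
#' (eps0 eps_r)` against which the full Gouy-Chapman expression linearises.
#'
#' @param env An [electrolyte()] object.
#' @return Debye length in m.
#' @export
debye_length <- function(env = electrolyte()) {
  stopifnot_electrolyte(env)
  cst <- physical_constants()
  kT <- cst$k_B * env$temperature
  n <- ionic_number_density(env$ionic_strength)
  sqrt(cst$epsilon_0 * env$relative_permittivity * kT / (2 * n * cst$e^2))
}

#' Interfacial pH from the Boltzmann distribution
#'
#' Protons equilibrate across the double layer, so the pH directly at a
#' charged interface differs from the bulk by the Boltzmann factor of the
#' head-group potential: `pH_I = pH_B + e psi / (kT ln 10)`. A negative
#' potential accumulates protons and lowers the interfacial pH.
#'
#' @param psi Head-group potential in mV.
#' @param env An [electrolyte()] object supplying temperature and bulk pH.
#' @return Interfacial pH (vectorised over `psi`).
#' @examples
#' interfacial_ph(-117, electrolyte(bulk_ph = 7))
#' @export
interfacial_ph <- function(psi, env = electrolyte()) {
  stopifnot_electrolyte(env)
  env$bulk_ph + ph_per_mV(env) * psi
}

# Boltzmann/Nernst slope: pH units per mV at the environment's temperature
ph_per_mV <- function(env) {
  cst <- physical_constants()
  cst$e * mV_to_V / (cst$k_B * env$temperature * log(10))
}

#' Shift of interfacial pH between two potential states
#'
#' Applies the Boltzmann relation to a change of head-group potential:
#' `delta_pH_I = e (psi_end - psi_start) / (kT ln 10)`. A potential that
#' becomes less negative (e.g. during an expansion pulse) releases protons
#' from the interface and raises the interfacial pH.
#'
#' @param psi_start,psi_end Head-group potentials in mV.
#' @param env An [electrolyte()] object (temperature only is used).
#' @return Interfacial pH change in pH units (signed).
#' @examples
#' interfacial_ph_shift(-117.1, -112.6)   # about +0.08
#' @export
interfacial_ph_shift <- function(psi_start, psi_end, env = electrolyte()) {
  stopifnot_electrolyte(env)
  ph_per_mV(env) * (psi_end - psi_start)
}

#' State of the charged interface
#'
#' Bundles the derived electrostatic quantities for a monolayer at a given
#' area per molecule and dissociation degree: surface charge density,
#' Gouy-Chapman head-group potential and Boltzmann interfacial pH.
#'
#' @inheritParams gouy_chapman_potential
#' @return A tibble with one row per input element and columns `area`,
#'   `alpha`, `sigma` (C/m^2), `psi` (mV), `interfacial_ph`.
#' @examples
#' interface_state(c(75, 82), 0.88, electrolyte())
#' @export
interface_state <- function(area, alpha, env = electrolyte()) {
  stopifnot_electrolyte(env)
  psi <- gouy_chapman_potential(area, alpha, env)
  tibble(
    area = area,
    alpha = alpha,
    sigma = surface_charge_density(area, alpha),
    psi = psi,
    interfacial_ph = interfacial_ph(psi, env)
  )
}

#' Decompose the total surface potential
#'
#' The Kelvin-probe surface potential of a monolayer is the sum of a
#' hydrophilic (head group / water) contribution `psi` and a hydrophobic
#' (tail / air) contribution, so `v_tail = v_total - psi` exactly.
#'
#' @param v_total Total surface potential in mV.
#' @param psi Head-group potential in mV.
#' @return A tibble with columns `v_total`, `psi`, `v_tail` (all mV).
#' @examples
#' decompose_potential(-300, -117)
#' @export
decompose_potential <- function(v_total, psi) {
  tibble(v_total = v_total, psi = psi, v_tail = v_total - psi)
}

#' Head-group potential change for the titrating fraction
#'
#' A measured total-surface-potential difference between the fully
#' protonated and fully deprotonated states of the head group, at fixed
#' molecular area, isolates the protonation contribution (the tail potential
#' is constant at fixed area). Scaling it by the dissociation degree at the
#' working pH gives the head-group potential change actually realised:
#' `alpha * delta_v_total_full`.
#'
#' @param delta_v_total_full Full protonation-to-deprotonation change of the
#'   total surface potential in mV (typically negative for an acidic lipid).
#' @param alpha Dissociation degree in `[0, 1]`.
#' @return Potential change in mV.
#' @examples
#' protonation_potential_change(-180, 0.88)   # -158.4 mV
#' @export
protonation_potential_change <- function(delta_v_total_full, alpha) {
  if (any(alpha < 0) || any(alpha > 1)) abort("`alpha` must lie in [0, 1].")
  alpha * delta_v_total_full
}
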