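# Shared fixtures and independent oracles.

# reference sigmoid of the DMPS titration (transition pressure vs pH)
ref_sigmoid <- list(A1 = 4.5, A2 = 24.4, x0 = 5.4, dx = 0.83)

ref_ph_grid <- seq(3, 9, by = 0.5)

# plain-formula sigmoid, independent of the package implementation
oracle_sigmoid <- function(ph, p) {
  p$A2 + (p$A1 - p$A2) / (1 + exp((ph - p$x0) / p$dx))
}

# analytic isotherms with known compressibility
exp_isotherm <- function(A0 = 100, k = 0.02, p = seq(0, 30, by = 0.25)) {
  isotherm(tibble::tibble(pressure = p, area = A0 * exp(-k * p)))
}

linear_isotherm <- function(A0 = 100, s = 2, p = seq(0, 30, by = 0.5)) {
  isotherm(tibble::tibble(pressure = p, area = A0 - s * p))
}

# Grahame relation sigma(psi), solved numerically for psi: the brute-force
# double-layer oracle (psi in volts here; returns mV)
grahame_psi_oracle <- function(sigma, ionic_strength, temperature = 298.15,
                               eps_r = 78.5) {
  cst <- list(e = 1.602176634e-19, k_B = 1.380649e-23,
              N_A = 6.02214076e23, eps0 = 8.8541878128e-12)
  kT <- cst$k_B * temperature
  n <- cst$N_A * ionic_strength * 1e3
  pref <- sqrt(8 * cst$eps0 * eps_r * kT * n)
  f <- function(psi) pref * sinh(cst$e * psi / (2 * kT)) - sigma
  stats::uniroot(f, c(-2, 2), tol = 1e-12)$root * 1e3
}

# noiseless truth for exact round-trip checks
noiseless_truth <- function(...) {
  synthetic_truth(noise_sd = NULL, ...)
}

ref_calibration <- function(ph_lo = 6.4, ph_hi = 7.6) {
  calibration_line(slope = 0.6, intercept = -1.9,
                   valid_ph_range = c(ph_lo, ph_hi),
                   valid_pressure_range = c(5, 8))
}
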