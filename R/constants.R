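#' Physical constants (CODATA 2018)
#'
#' Exact SI values of the constants used by the electrostatic and acoustic
#' calculations: elementary charge `e` (C), Boltzmann constant `k_B` (J/K),
#' Avogadro constant `N_A` (1/mol) and vacuum permittivity `epsilon_0` (F/m).
#'
#' @return A named list with elements `e`, `k_B`, `N_A`, `epsilon_0`.
#' @examples
#' physical_constants()$e
#' @export
physical_constants <- function() {
  list(
    e         = 1.602176634e-19,
    k_B       = 1.380649e-23,
    N_A       = 6.02214076e23,
    epsilon_0 = 8.8541878128e-12
  )
}

# unit conversions used at I/O and formula boundaries
A2_to_m2 <- 1e-20      # angstrom^2 -> m^2
mN_per_m_to_N_per_m <- 1e-3
mV_to_V <- 1e-3
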