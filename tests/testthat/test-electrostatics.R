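test_that("Gouy-Chapman potential matches a brute-force Grahame inversion", {
  env <- electrolyte()
  grid <- expand.grid(area = c(40, 60, 75, 82, 100, 120),
                      alpha = c(0.01, 0.1, 0.5, 0.88, 1),
                      ionic = c(0.01, 0.05, 0.11, 0.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    e_i <- electrolyte(ionic_strength = g$ionic)
    sigma <- surface_charge_density(g$area, g$alpha)
    psi <- gouy_chapman_potential(g$area, g$alpha, e_i)
    psi_oracle <- grahame_psi_oracle(sigma, g$ionic)
    expect_lt(abs(psi - psi_oracle), 0.01)
  }
})

test_that("the DMPS worked-example potentials are reproduced", {
  env <- electrolyte(ionic_strength = 0.11, temperature = 298.15,
                     relative_permittivity = 78.5)
  psi <- gouy_chapman_potential(c(75, 82), 0.88, env)
  expect_equal(round(abs(psi[1])), 117)
  expect_equal(round(abs(psi[2])), 113)
  expect_equal(round(psi[2] - psi[1]), 4)
  expect_true(all(psi < 0))
})

test_that("zero charge gives zero potential and the sign convention holds", {
  env <- electrolyte()
  expect_identical(gouy_chapman_potential(75, 0, env), 0)
  expect_identical(surface_charge_density(75, 0), 0)
  expect_lt(surface_charge_density(75, 0.5), 0)
  expect_lt(gouy_chapman_potential(75, 0.5, env), 0)
})

test_that("small-charge potential linearises to the Debye-Hueckel form", {
  env <- electrolyte()
  cst <- physical_constants()
  alpha <- 0.001
  sigma <- surface_charge_density(75, alpha)
  psi_lin_mV <- sigma * debye_length(env) /
    (cst$epsilon_0 * env$relative_permittivity) * 1e3
  psi <- gouy_chapman_potential(75, alpha, env)
  expect_lt(abs(psi - psi_lin_mV) / abs(psi_lin_mV), 0.005)
})

test_that("|psi| is monotone in area, ionic strength and alpha", {
  areas <- seq(40, 120, by = 10)
  psi_area <- abs(gouy_chapman_potential(areas, 0.88, electrolyte()))
  expect_true(all(diff(psi_area) < 0))

  ionics <- c(0.01, 0.05, 0.11, 0.3, 0.5)
  psi_ion <- vapply(ionics, function(I) {
    abs(gouy_chapman_potential(75, 0.88, electrolyte(ionic_strength = I)))
  }, numeric(1))
  expect_true(all(diff(psi_ion) < 0))

  alphas <- seq(0.1, 1, by = 0.1)
  psi_a <- abs(gouy_chapman_potential(75, alphas, electrolyte()))
  expect_true(all(diff(psi_a) > 0))
})

test_that("the Boltzmann pH shift has the exact Nernst slope at any temperature", {
  cst <- physical_constants()
  for (temp in c(278.15, 293.15, 298.15, 310.15)) {
    env <- electrolyte(temperature = temp)
    slope_per_mV <- interfacial_ph_shift(0, 1, env)
    nernst <- cst$e * 1e-3 / (cst$k_B * temp * log(10))
    expect_equal(slope_per_mV, nernst, tolerance = 1e-12)
  }
  # 59.16 mV per pH unit at 25 degC
  expect_equal(interfacial_ph_shift(0, 59.16, electrolyte()), 1.0,
               tolerance = 1e-4)
})

test_that("pH shifts are additive over concatenated potential legs", {
  env <- electrolyte()
  psis <- c(-117.1, -80, -20, 5)
  total <- interfacial_ph_shift(psis[1], psis[4], env)
  legs <- interfacial_ph_shift(psis[1], psis[2], env) +
    interfacial_ph_shift(psis[2], psis[3], env) +
    interfacial_ph_shift(psis[3], psis[4], env)
  expect_equal(total, legs, tolerance = 1e-12)
  expect_identical(interfacial_ph_shift(-50, -50, env), 0)
  # less negative potential raises interfacial pH
  expect_gt(interfacial_ph_shift(-117, -113, env), 0)
})

test_that("the worked-example pH shift is +0.1 at one-decimal rounding", {
  env <- electrolyte()
  psi <- gouy_chapman_potential(c(75, 82), 0.88, env)
  dph <- interfacial_ph_shift(psi[1], psi[2], env)
  expect_equal(round(dph, 1), 0.1)
})

test_that("potential decomposition is an exact arithmetic identity", {
  d <- decompose_potential(-300, -117)
  expect_equal(d$v_tail, -183)
  expect_equal(d$v_total, d$v_tail + d$psi)
  d0 <- decompose_potential(0, 0)
  expect_equal(d0$v_tail, 0)
  # recomposition
  d2 <- decompose_potential(d$v_tail + d$psi, d$psi)
  expect_equal(d2$v_total, d$v_total)
})

test_that("protonation potential change scales the full change by alpha", {
  expect_equal(protonation_potential_change(-180, 0.88), -158.4)
  expect_equal(round(protonation_potential_change(-180, 0.88)), -158)
  expect_identical(protonation_potential_change(-180, 0), 0)
  expect_identical(protonation_potential_change(-180, 1), -180)
  expect_error(protonation_potential_change(-180, 1.2), "alpha")
})

test_that("interface_state bundles charge, potential and interfacial pH consistently", {
  env <- electrolyte(bulk_ph = 7)
  st <- interface_state(c(75, 82), 0.88, env)
  expect_equal(nrow(st), 2)
  expect_equal(st$psi, gouy_chapman_potential(c(75, 82), 0.88, env))
  expect_equal(st$interfacial_ph,
               7 + interfacial_ph_shift(0, st$psi, env))
  expect_true(all(st$interfacial_ph < 7))  # negative surface accumulates protons
})

test_that("invalid environments are rejected", {
  expect_error(electrolyte(ionic_strength = 0), "ionic_strength")
  expect_error(electrolyte(relative_permittivity = 200), "permittivity")
  expect_error(electrolyte(temperature = -1), "temperature")
  expect_error(gouy_chapman_potential(-5, 0.5), "area")
  expect_error(gouy_chapman_potential(75, 1.5), "alpha")
})
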