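test_that("compressibility matches the analytic derivative on closed-form isotherms", {
  # exponential: kappa_T is identically k
  k <- 0.02
  kp <- compressibility_profile(exp_isotherm(k = k), smoothing = 0)
  expect_lt(max(abs(kp$kappa_T - k) / k), 1e-3)

  # linear: kappa_T = s/(A0 - s*pi), increasing in pressure
  A0 <- 100; s <- 2
  kp2 <- compressibility_profile(linear_isotherm(A0 = A0, s = s), smoothing = 0)
  oracle <- s / (A0 - s * kp2$pressure)
  expect_lt(max(abs(kp2$kappa_T - oracle) / oracle), 1e-3)
  expect_true(all(diff(kp2$kappa_T) > 0))
})

test_that("isotherm validation enforces monotonicity, units and size", {
  expect_error(isotherm(tibble::tibble(pressure = 1:5, area = 50 - (1:5))),
               "10 records")
  bad <- tibble::tibble(pressure = seq(1, 12), area = c(seq(100, 58, length.out = 11), 90))
  expect_error(isotherm(bad), "increases with pressure")
  expect_error(isotherm(tibble::tibble(pressure = c(-1, 1:11),
                                       area = seq(100, 45, length.out = 12))),
               "pressure")
})

test_that("the compressibility maximum locates the generated transition pressure", {
  grid <- seq(0.5, 35, by = 0.25)
  iso <- make_isotherm(eos_params(), subphase_ph = 7, pressure_grid = grid)
  kp <- compressibility_profile(iso, smoothing = 0)
  pt <- find_transition_pressure(kp)
  expect_lt(abs(pt - attr(iso, "true_transition_pressure")), 0.25 + 1e-9)
})

test_that("transition pressures are recovered across seeded noise realisations", {
  grid <- seq(0.5, 35, by = 0.25)
  eos <- eos_params()
  errs <- vapply(1:50, function(s) {
    iso <- make_isotherm(eos, 7, grid, noise_sd = 0.1, seed = s)
    kp <- compressibility_profile(iso)
    abs(find_transition_pressure(kp) - attr(iso, "true_transition_pressure"))
  }, numeric(1))
  expect_true(all(errs <= 0.25 + 1e-9))
})

test_that("a monotone compressibility without interior maximum is an error", {
  kp <- compressibility_profile(linear_isotherm(), smoothing = 0)
  expect_error(find_transition_pressure(kp), "boundary")
})

test_that("transition-pressure ties break toward the lower pressure", {
  kp <- tibble::tibble(pressure = c(10, 15, 20, 25),
                       kappa_T = c(0.01, 0.05, 0.05, 0.01))
  class(kp) <- c("compressibility_profile", class(kp))
  expect_equal(find_transition_pressure(kp), 15)
})

test_that("sound velocity follows c = (rho kappa)^(-1/2) with lateral lipid density", {
  # hand evaluation: rho = 1.5e-6 kg/m^2 and kappa = 0.05 (mN/m)^-1 -> 115.47 m/s
  expect_equal(1 / sqrt(1.5e-6 * 0.05 / 1e-3), 115.47, tolerance = 1e-4)

  k <- 0.02
  iso <- exp_isotherm(k = k)
  kp <- compressibility_profile(iso, smoothing = 0)
  vp <- sound_velocity_profile(kp, iso)
  # direct recomputation at one interior point
  cst <- physical_constants()
  i <- 50
  area <- iso$area[iso$pressure == vp$pressure[i]]
  rho <- 679.9e-3 / (cst$N_A * area * 1e-20)
  expect_equal(vp$velocity[i], 1 / sqrt(rho * kp$kappa_T[i] / 1e-3),
               tolerance = 1e-10)

  # doubling the effective density scales velocity by 1/sqrt(2)
  vp2 <- sound_velocity_profile(kp, iso, effective_density_factor = 2)
  expect_equal(vp2$velocity, vp$velocity / sqrt(2), tolerance = 1e-12)
})

test_that("velocity minimum and compressibility maximum coincide", {
  grid <- seq(0.5, 35, by = 0.25)
  iso <- make_isotherm(eos_params(), 7, grid)
  kp <- compressibility_profile(iso, smoothing = 0)
  vp <- sound_velocity_profile(kp, iso)
  p_kmax <- kp$pressure[which.max(kp$kappa_T)]
  p_vmin <- vp$pressure[which.min(vp$velocity)]
  expect_lte(abs(p_kmax - p_vmin), 0.25 + 1e-9)
})

test_that("pressure-to-area mapping inverts the isotherm", {
  s <- 2
  iso <- linear_isotherm(A0 = 100, s = s)
  m <- pressure_to_area(iso, p_start = 10, delta_p = -2.4)
  expect_equal(m$area_end - m$area_start, -s * (-2.4), tolerance = 1e-9)
  expect_gt(m$area_end, m$area_start)   # expansion increases area

  m0 <- pressure_to_area(iso, 10, 0)
  expect_equal(m0$area_end, m0$area_start)
  expect_error(pressure_to_area(iso, 29, 5), "outside")
})

test_that("potential-pressure composition is exact for linear curves", {
  s <- 2; A0 <- 100; b <- -3; a <- 50
  iso <- linear_isotherm(A0 = A0, s = s)
  vcurve <- tibble::tibble(area = seq(40, 100, 5),
                           v_total = a + b * seq(40, 100, 5))
  map <- potential_pressure_map(iso, vcurve)
  # composed slope is -b*s
  pred <- quasi_static_potential_prediction(map, p_baseline = 10, amplitude = -2.4)
  expect_equal(pred, -b * s * (-2.4), tolerance = 1e-9)
  expect_equal(quasi_static_potential_prediction(map, 10, 0), 0)

  const <- tibble::tibble(area = seq(40, 100, 5), v_total = rep(7, 13))
  map_c <- potential_pressure_map(iso, const)
  expect_true(all(abs(map_c$v_total - 7) < 1e-12))

  disjoint <- tibble::tibble(area = c(300, 310, 320, 330), v_total = 1:4)
  expect_error(potential_pressure_map(iso, disjoint), "disjoint")
})

test_that("smoothing keeps compressibility positive on noisy isotherms", {
  iso <- make_isotherm(eos_params(), 7, seq(0.5, 35, 0.25),
                       noise_sd = 0.1, seed = 42)
  kp <- compressibility_profile(iso)   # GCV-selected smoothing
  expect_true(all(kp$kappa_T > 0))
  expect_true(all(is.finite(kp$kappa_T)))
})
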