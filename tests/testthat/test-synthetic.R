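test_that("noiseless isotherms equal the EOS closed form exactly", {
  eos <- eos_params()
  grid <- seq(0.5, 35, by = 0.25)
  iso <- make_isotherm(eos, subphase_ph = 7, pressure_grid = grid)
  pi_T <- oracle_sigmoid(7, ref_sigmoid)
  expect_equal(iso$area, eos_area(eos, grid, pi_T), tolerance = 1e-12)
  expect_equal(attr(iso, "true_transition_pressure"), pi_T, tolerance = 1e-12)
})

test_that("generated isotherms stay strictly decreasing even with noise", {
  eos <- eos_params()
  grid <- seq(0.5, 35, by = 0.25)
  for (s in c(1, 9, 77)) {
    iso <- make_isotherm(eos, 7, grid, noise_sd = 0.3, seed = s)
    expect_true(all(diff(iso$area) < 0))
  }
})

test_that("the pH limits of the transition sigmoid set the plateau separation", {
  eos <- eos_params()
  grid <- seq(0.5, 35, by = 0.25)
  iso_hi <- make_isotherm(eos, 9, grid)
  iso_lo <- make_isotherm(eos, 1.5, grid)
  d <- attr(iso_hi, "true_transition_pressure") -
    attr(iso_lo, "true_transition_pressure")
  # close to the full sigmoid swing A2 - A1, limited by the finite pH range
  swing <- oracle_sigmoid(9, ref_sigmoid) - oracle_sigmoid(1.5, ref_sigmoid)
  expect_equal(d, swing, tolerance = 1e-12)
  expect_lt(abs(swing - (ref_sigmoid$A2 - ref_sigmoid$A1)), 0.5)
})

test_that("transition points sit on the sigmoid and respect the seed contract", {
  pts <- make_transition_points(ref_sigmoid, ref_ph_grid, noise_sd = 0)
  expect_equal(pts$transition_pressure,
               oracle_sigmoid(ref_ph_grid, ref_sigmoid), tolerance = 1e-12)
  # midpoint: the curve passes through (x0, (A1+A2)/2)
  mid <- make_transition_points(ref_sigmoid, c(3, 4, 5.4, 7, 9), noise_sd = 0)
  expect_equal(mid$transition_pressure[mid$ph == 5.4],
               (ref_sigmoid$A1 + ref_sigmoid$A2) / 2, tolerance = 1e-12)
  expect_equal(oracle_sigmoid(5.4, ref_sigmoid),
               (ref_sigmoid$A1 + ref_sigmoid$A2) / 2, tolerance = 1e-12)

  a <- make_transition_points(ref_sigmoid, ref_ph_grid, 0.2, seed = 1)
  b <- make_transition_points(ref_sigmoid, ref_ph_grid, 0.2, seed = 2)
  a2 <- make_transition_points(ref_sigmoid, ref_ph_grid, 0.2, seed = 1)
  expect_false(isTRUE(all.equal(a$transition_pressure, b$transition_pressure)))
  expect_identical(a$transition_pressure, a2$transition_pressure)
  expect_error(make_transition_points(ref_sigmoid, numeric(0)), "non-empty")
})

test_that("pulse traces impose delay, damping and the exact shifted-copy identity", {
  truth <- noiseless_truth(pulse_velocity = 0.6, pulse_amplitude_s1 = 2.0,
                           damping_ratio = 0.55)
  tr <- make_pulse_traces(truth, sensor_separation = 0.15,
                          sampling_rate = 10000, seed = 1)
  expect_equal(max(tr$p1) - tr$p1[1], 2.0, tolerance = 1e-9)
  expect_equal(max(tr$p2) - tr$p2[1], 1.1, tolerance = 1e-9)
  # damping_ratio 1: channel 2 is an exact shifted copy of channel 1
  tr1 <- make_pulse_traces(noiseless_truth(damping_ratio = 1), seed = 1)
  shift <- round(0.15 / 0.6 * 10000)
  n <- nrow(tr1)
  expect_equal(tr1$p2[(shift + 1):n], tr1$p1[1:(n - shift)], tolerance = 1e-12)
})

test_that("trace generation rejects impossible geometry and timing", {
  expect_error(make_pulse_traces(noiseless_truth(), sensor_separation = -1),
               "separation")
  expect_error(make_pulse_traces(noiseless_truth(pulse_velocity = 0.01),
                                 duration = 2),
               "[Dd]uration")
  expect_error(synthetic_truth(damping_ratio = 0), "damping_ratio")
  expect_error(synthetic_truth(noise_sd = c(bogus = 1)), "noise_sd")
  expect_error(synthetic_truth(noise_sd = c(p1 = -1)), ">= 0")
})

test_that("channel noise has the requested standard deviation", {
  s <- 0.05
  noisy <- make_pulse_traces(synthetic_truth(noise_sd = c(p1 = s, p2 = s)),
                             seed = 3)
  clean <- make_pulse_traces(noiseless_truth(), seed = 3)
  resid <- noisy$p1 - clean$p1
  expect_gt(length(resid), 1000)
  expect_lt(abs(sd(resid) - s) / s, 0.2)
})

test_that("quantisation rounds to the sensor resolutions", {
  tr <- make_pulse_traces(noiseless_truth(), seed = 1, quantize = TRUE)
  expect_true(all(abs(tr$p1 / 0.01 - round(tr$p1 / 0.01)) < 1e-9))
  expect_true(all(abs(tr$v_total / 5 - round(tr$v_total / 5)) < 1e-9))
})

test_that("fluorescence traces follow the calibration line exactly when noiseless", {
  cal <- ref_calibration()
  truth <- noiseless_truth(delta_ph_interface = 0.6)
  tr <- make_fluorescence_trace(truth, cal, baseline_ph = 7, seed = 5)
  i_ratio <- tr$i535 / tr$i605
  # peak ratio: linear interpolation of the calibration at pH 7.6
  expect_equal(max(i_ratio), -1.9 + 0.6 * 7.6, tolerance = 1e-5)
  expect_equal(i_ratio[1], -1.9 + 0.6 * 7.0, tolerance = 1e-9)

  # delta_ph = 0 gives a constant ratio
  tr0 <- make_fluorescence_trace(noiseless_truth(delta_ph_interface = 0),
                                 cal, baseline_ph = 7, seed = 5)
  expect_lt(diff(range(tr0$i535 / tr0$i605)), 1e-12)

  # seed contract: identical noiseless component under different seeds
  tr_a <- make_fluorescence_trace(truth, cal, baseline_ph = 7, seed = 1)
  tr_b <- make_fluorescence_trace(truth, cal, baseline_ph = 7, seed = 2)
  expect_identical(tr_a$i535, tr_b$i535)

  expect_error(
    make_fluorescence_trace(noiseless_truth(delta_ph_interface = 2), cal,
                            baseline_ph = 7, seed = 1),
    "validity range"
  )
})

test_that("experiment bundles round-trip through every reader and are byte-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- make_experiment_bundle(d1, seed = 11)
  b2 <- make_experiment_bundle(d2, seed = 11)

  for (nm in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]),
                     label = paste("bundle file", nm))
  }

  iso_back <- read_isotherm(b1$paths$isotherm_ph7, subphase_ph = 7)
  expect_equal(iso_back$area, b1$isotherms$ph7$area, tolerance = 1e-9)

  tit_back <- read_transition_curve(b1$paths$titration)
  expect_equal(tit_back$transition_pressure,
               b1$titration$transition_pressure, tolerance = 1e-9)

  tr_back <- read_pulse_trace(b1$paths$pressure_trace)
  expect_equal(tr_back$p1, b1$pressure_trace$p1, tolerance = 1e-9)
  expect_equal(attr(tr_back, "sampling_rate"),
               attr(b1$pressure_trace, "sampling_rate"), tolerance = 1e-6)

  ftr_back <- read_pulse_trace(b1$paths$fluorescence_trace)
  expect_true(all(c("i535", "i605") %in% names(ftr_back)))

  cal_back <- read_calibration_points(b1$paths$calibration)
  expect_equal(cal_back$i_ratio, b1$calibration_points$i_ratio, tolerance = 1e-9)

  truth_back <- read_truth(b1$paths$truth)
  expect_equal(truth_back$pulse_velocity, b1$truth$pulse_velocity)
  expect_equal(unlist(truth_back$noise_sd), unlist(b1$truth$noise_sd))

  expect_error(make_experiment_bundle(withr::local_tempdir(), seed = 1,
                                      config = list(nope = 1)),
               "Unknown bundle config")
})
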