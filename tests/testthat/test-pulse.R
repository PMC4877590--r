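test_that("both arrival methods recover an imposed 0.25 s delay exactly", {
  truth <- noiseless_truth(pulse_velocity = 0.6)
  tr <- make_pulse_traces(truth, sensor_separation = 0.15,
                          sampling_rate = 10000, seed = 1)
  dt <- 1e-4
  for (m in c("threshold", "xcorr")) {
    arr <- detect_arrivals(tr, method = m)
    expect_lt(abs((arr$t2 - arr$t1) - 0.25), dt + 1e-12)
  }
})

test_that("an identical channel pair (zero delay) is rejected", {
  time <- seq(0, 2, by = 1e-3)
  p <- 8 + 2 * exp(-(time - 0.5)^2 / (2 * 0.05^2))
  tr <- pulse_trace(tibble::tibble(time = time, p1 = p, p2 = p))
  expect_error(detect_arrivals(tr), "delay")
})

test_that("a flat noiseless trace has no pulse", {
  time <- seq(0, 1, by = 1e-3)
  tr <- pulse_trace(tibble::tibble(time = time, p1 = rep(8, length(time)),
                                   p2 = rep(8, length(time))))
  expect_error(detect_arrivals(tr), "No pulse")
})

test_that("features reproduce a noiseless truth exactly", {
  truth <- noiseless_truth(pulse_velocity = 0.6, pulse_amplitude_s1 = -2.0,
                           damping_ratio = 0.55)
  tr <- make_pulse_traces(truth, seed = 1)
  f <- pulse_features(tr)
  expect_equal(f$velocity, 0.6, tolerance = 1e-6)
  expect_equal(f$amplitude_1, -2.0, tolerance = 1e-9)
  expect_equal(f$amplitude_2, -1.1, tolerance = 1e-9)
  expect_equal(f$damping_ratio, 0.55, tolerance = 1e-9)
  expect_lt(f$amplitude_1, 0)   # expansion pulses are negative
  expect_gt(f$relaxation_time, 0)
})

test_that("threshold and xcorr agree on symmetric noiseless pulses", {
  truth <- noiseless_truth()
  tr <- make_pulse_traces(truth, pulse_shape = "gaussian", seed = 1)
  d_thr <- with(detect_arrivals(tr, "threshold"), t2 - t1)
  d_xc <- with(detect_arrivals(tr, "xcorr"), t2 - t1)
  dt <- 1 / attr(tr, "sampling_rate")
  expect_lt(abs(d_thr - d_xc), 3 * dt)
})

test_that("velocity recovery stays within 2% median error across velocity and SNR", {
  grid <- expand.grid(v = c(0.3, 0.6, 1.0, 1.4), snr = c(5, 10, 50))
  for (i in seq_len(nrow(grid))) {
    v <- grid$v[i]; snr <- grid$snr[i]
    rel_err <- vapply(1:50, function(s) {
      truth <- synthetic_truth(pulse_velocity = v,
                               pulse_amplitude_s1 = -2.0,
                               damping_ratio = 0.55,
                               noise_sd = c(p1 = 2 / snr, p2 = 1.1 / snr))
      tr <- make_pulse_traces(truth, sampling_rate = 1000, duration = 1.8,
                              t_excite = 0.2, seed = s)
      f <- pulse_features(tr, method = "xcorr", smooth_window = 21)
      abs(f$velocity - v) / v
    }, numeric(1))
    expect_lt(median(rel_err), 0.02)
  }
})

test_that("cross-correlation delay is accurate to two samples at moderate noise", {
  truth <- synthetic_truth(pulse_velocity = 0.6, pulse_amplitude_s1 = -2.0,
                           damping_ratio = 0.55,
                           noise_sd = c(p1 = 0.2, p2 = 0.11))   # SNR 10
  errs <- vapply(1:100, function(s) {
    tr <- make_pulse_traces(truth, sampling_rate = 1000, duration = 1.8,
                            t_excite = 0.2, seed = s)
    arr <- detect_arrivals(tr, "xcorr", smooth_window = 21)
    abs((arr$t2 - arr$t1) - 0.25) * 1000   # in samples
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 2)
})

test_that("damping is recovered within 5% at SNR 10 and above", {
  truth <- synthetic_truth(pulse_velocity = 0.6, pulse_amplitude_s1 = -2.0,
                           damping_ratio = 0.55,
                           noise_sd = c(p1 = 0.2, p2 = 0.11))
  errs <- vapply(1:50, function(s) {
    tr <- make_pulse_traces(truth, sampling_rate = 1000, duration = 1.8,
                            t_excite = 0.2, seed = s)
    abs(pulse_features(tr, smooth_window = 51)$damping_ratio - 0.55) / 0.55
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("trace validation enforces uniform sampling and geometry", {
  t_bad <- c(seq(0, 1, by = 0.01), 1.5)
  expect_error(pulse_trace(tibble::tibble(time = t_bad,
                                          p1 = seq_along(t_bad),
                                          p2 = seq_along(t_bad))),
               "uniformly")
  expect_error(pulse_trace(tibble::tibble(time = seq(0, 1, 0.01),
                                          p1 = 1:101, p2 = 1:101),
                           sensor_separation = 0),
               "separation")
})
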