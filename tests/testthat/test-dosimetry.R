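test_that("pulse-average intensity follows the plane-wave relation", {
  water <- medium_preset("water")
  tumor <- medium_preset("tumor")
  # hand-computed references: p^2 / (2 rho c) / 1e4
  expect_equal(isppa(4.53e6, water), 4.53e6^2 / (2 * 1000 * 1480) / 1e4)
  expect_equal(isppa(3.0e6, tumor), 3.0e6^2 / (2 * 1060 * 1521) / 1e4)
  expect_identical(isppa(0, water), 0)
  # quadratic scaling
  expect_equal(isppa(2 * 1e6, water), 4 * isppa(1e6, water))
  # direct property interface
  expect_equal(isppa(1e6, density_kg_m3 = 1000, sound_speed_m_s = 1480),
               isppa(1e6, water))
})

test_that("temporal-average intensity is the duty-cycled pulse average", {
  pulse <- pulse_params(60, 1.45e-3)
  expect_equal(pulse$duty_cycle, 0.087)
  expect_equal(ispta(279.1, pulse), 279.1 * 0.087)
  expect_equal(ispta(136.8, pulse), 136.8 * 0.087)
  cw <- pulse_params(10, 0.1)  # duty cycle 1
  expect_equal(ispta(42, cw), 42)
  expect_error(pulse_params(60, 0.02), "duty cycle")
  # ratio equals duty cycle for arbitrary inputs
  for (ip in c(0.5, 7, 1234)) {
    expect_equal(ispta(ip, pulse) / ip, pulse$duty_cycle)
  }
})

test_that("mechanical index is pressure over root frequency", {
  expect_equal(mechanical_index(3.0, 20.7), 3.0 / sqrt(20.7))
  expect_equal(round(mechanical_index(3.0, 20.7), 2), 0.66)
  expect_equal(round(mechanical_index(2.1, 20.7), 2), 0.46)
  expect_identical(mechanical_index(0, 20.7), 0)
})

test_that("thermal dose follows the piecewise rate constants", {
  expect_equal(cem43_const(43, 7), 7)            # identity at reference
  expect_equal(cem43_const(44, 7), 14)           # doubling above
  expect_equal(cem43_const(42, 8), 2)            # quartering below
  # the reference low-temperature exposure is tens of milliseconds
  expect_equal(cem43_const(35.6, 11.5), 11.5 * 0.25^7.4)
  rec <- thermal_record(c(0, 5, 11.5), c(40, 40, 40))
  expect_equal(cem43(rec), cem43_const(40, 11.5))
})

test_that("thermal dose is additive and monotone", {
  # two records sharing their junction sample concatenate additively
  t1 <- thermal_record(seq(0, 5, by = 0.5), seq(40, 45, by = 0.5))
  t2 <- thermal_record(seq(5, 9, by = 0.5), seq(45, 41, by = -0.5))
  joined <- thermal_record(c(t1$time_min, t2$time_min[-1]),
                           c(t1$temp_c, t2$temp_c[-1]))
  expect_equal(cem43(joined), cem43(t1) + cem43(t2))
  # monotone in temperature and duration
  hotter <- thermal_record(t1$time_min, t1$temp_c + 1)
  expect_gt(cem43(hotter), cem43(t1))
  base <- thermal_record(seq(0, 5, by = 0.5), rep(41, 11))
  longer <- thermal_record(seq(0, 6, by = 0.5), rep(41, 13))
  expect_gt(cem43(longer), cem43(base))
  expect_error(thermal_record(c(1, 1), c(40, 40)), "increasing")
})

test_that("safety report applies strict-less limits with categories", {
  pulse <- pulse_params(60, 1.45e-3)
  tumor <- medium_preset("tumor")
  hot <- dose_metrics(3.0, tumor, pulse)
  rep_hot <- safety_report(hot)
  expect_equal(rep_hot$pass, c(FALSE, FALSE, TRUE))
  # treatment sits close to the pulse-average limit, far above the
  # temporal-average limit, far below the MI limit
  expect_equal(rep_hot$category, c("close", "higher", "lower"))

  cold <- dose_metrics(0, tumor, pulse)
  expect_true(all(safety_report(cold)$pass))

  at_limit <- dose_metrics(sqrt(1.9^2 * 20.7), tumor, pulse)
  expect_false(safety_report(at_limit)$pass[3])  # MI exactly 1.9 fails
})

test_that("insertion-loss estimator inverts its forward model", {
  expect_equal(attenuation_from_insertion_loss(exp(0.3924), 1, 0.4, 0.110),
               0.110 + 0.3924 / 0.4)
  expect_equal(attenuation_from_insertion_loss(3, 3, 1, 0.2), 0.2)
  expect_error(attenuation_from_insertion_loss(0, 1, 1), "positive")
  # synthesis round trip on a waveform
  alpha <- 0.847
  d <- 0.63
  ref <- synth_pulsed_waveform(20.7e6, n_cycles = 10, amplitude = 2,
                               n_bursts = 1, duration_s = 2e-6)
  through <- apply_attenuation(ref, alpha, d)
  est <- attenuation_from_insertion_loss(max(abs(ref$x)),
                                         max(abs(through$x)), d, 0)
  expect_equal(est, alpha, tolerance = 1e-6)
})

test_that("time-of-flight estimator inverts its forward model", {
  expect_equal(sound_speed_from_tof(0, 5, 1480), 1480)
  # delay back-computed from the tumor sound speed
  d_mm <- 5
  dt <- d_mm / 1000 / 1480 - d_mm / 1000 / 1521
  expect_equal(sound_speed_from_tof(dt, d_mm, 1480), 1521, tolerance = 1e-9)
  expect_error(sound_speed_from_tof(1, 5, 1480), "non-physical")
  # synthesized delayed burst, delay recovered by cross-correlation
  fs <- 16 * 20.7e6
  ref <- synth_pulsed_waveform(20.7e6, n_cycles = 5, n_bursts = 1,
                               duration_s = 3e-6, sample_rate_hz = fs)
  # sample replaces reference path: earlier arrival by dt
  delayed <- delay_waveform(ref, -dt)
  dt_est <- -estimate_delay(ref$x, delayed$x, fs)
  c_est <- sound_speed_from_tof(dt_est, d_mm, 1480)
  expect_equal(c_est, 1521, tolerance = 0.005)
})

test_that("dose metrics bundle is internally consistent", {
  pulse <- pulse_params(60, 1.45e-3)
  m <- dose_metrics(2.1, medium_preset("tumor"), pulse,
                    cem43_min = cem43_const(35.6, 11.5))
  expect_equal(m$ispta_w_cm2, m$isppa_w_cm2 * m$duty_cycle)
  expect_lte(m$ispta_w_cm2, m$isppa_w_cm2)
  expect_equal(m$mi, 2.1 / sqrt(20.7))
})
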