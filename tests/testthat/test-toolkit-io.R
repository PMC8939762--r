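test_that("waveform synthesis is deterministic under a fixed seed", {
  w1 <- synth_pulsed_waveform(20.7e6, n_cycles = 60, noise_sd = 0.1,
                              duration_s = 5e-6, seed = 42)
  w2 <- synth_pulsed_waveform(20.7e6, n_cycles = 60, noise_sd = 0.1,
                              duration_s = 5e-6, seed = 42)
  expect_identical(w1$x, w2$x)
  w3 <- synth_pulsed_waveform(20.7e6, n_cycles = 60, noise_sd = 0.1,
                              duration_s = 5e-6, seed = 43)
  expect_false(identical(w1$x, w3$x))
  # the caller's RNG stream is untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(synth_pulsed_waveform(20.7e6, noise_sd = 1,
                                               duration_s = 1e-6,
                                               seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("noise-free bursts have the requested amplitude and duration", {
  w <- synth_pulsed_waveform(20.7e6, n_cycles = 60, amplitude = 3,
                             prf_hz = 60, duration_s = 6e-6)
  expect_equal(max(abs(w$x)), 3, tolerance = 1e-3)
  # burst gate: 60 cycles of 20.7 MHz last 2.9 us
  on <- range(w$t_s[w$x != 0])
  expect_equal(diff(on), 60 / 20.7e6, tolerance = 0.02)
  expect_equal(diff(on), 2.9e-6, tolerance = 0.02)
})

test_that("undersampled synthesis is refused", {
  expect_error(synth_pulsed_waveform(20.7e6, sample_rate_hz = 5 * 20.7e6),
               "undersamples")
})

test_that("spectrum peaks at the carrier and conserves energy", {
  w <- synth_pulsed_waveform(20.7e6, n_cycles = 60, duration_s = 2e-5,
                             sample_rate_hz = 20 * 20.7e6)
  sp <- waveform_spectrum(w)
  bin <- w$sample_rate_hz / attr(sp, "n_fft")
  expect_lt(abs(attr(sp, "peak_hz") - 20.7e6), 2 * bin)
  expect_equal(dominant_frequency(w), attr(sp, "peak_hz"))
  # two-tone fixture resolves both injected frequencies
  w2 <- w
  w2$x <- sin(2 * pi * 5e6 * w$t_s) + sin(2 * pi * 14e6 * w$t_s)
  sp2 <- waveform_spectrum(w2)
  near <- function(f0) max(sp2$magnitude[abs(sp2$frequency_hz - f0) < 3 * bin])
  floor_mag <- stats::median(sp2$magnitude)
  expect_gt(near(5e6), 50 * floor_mag)
  expect_gt(near(14e6), 50 * floor_mag)
  # Parseval: the one-sided table accounts for the full record energy
  # (interior bins doubled; padded length from the attribute)
  n <- attr(sp, "n_fft")
  weights <- c(1, rep(2, nrow(sp) - 2), if (n %% 2 == 0) 1 else 2)
  expect_equal(sum(weights * (sp$magnitude * n)^2) / n, sum(w$x^2),
               tolerance = 1e-9)
})

test_that("pressure-voltage calibration recovers a constructed line", {
  v <- c(40, 80, 120, 160, 211)
  slope <- 4.53 / 211
  p <- slope * v
  fit <- pressure_voltage_fit(v, p)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_true(all(abs(fit$residuals) < 1e-12))
  expect_equal(fit$predict(211), 4.53, tolerance = 1e-9)
  expect_error(pressure_voltage_fit(rep(100, 3), c(1, 2, 3)), "degenerate")
  expect_error(pressure_voltage_fit(1, 1), "two")
})

test_that("config round-trips and is validated", {
  cfg <- list(focal_length_mm = 5, frequency_hz = 20.7e6,
              design_sound_speed_m_s = 1465, n_boundaries = 11L)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    save_config(cfg, path)
    back <- load_config(path)
    expect_equal(back[order(names(back))], cfg[order(names(cfg))],
                 tolerance = 1e-12)
  }
  expect_error(validate_config(list(focal_length = 5)), "focal_length")
  expect_error(validate_config(list(bananas_mm = 1)), "unknown")
  err <- tryCatch(validate_config(list(frequency = 1, voltage = 2)),
                  error = conditionMessage)
  expect_match(err, "frequency")
  expect_match(err, "voltage")
})

test_that("reports are reproducible and carry provenance", {
  cfgp <- withr::local_tempfile(fileext = ".yaml")
  save_config(list(frequency_hz = 20.7e6), cfgp)
  r1 <- withr::local_tempfile(fileext = ".json")
  r2 <- withr::local_tempfile(fileext = ".json")
  res <- list(isppa_w_cm2 = isppa(3e6, medium_preset("tumor")))
  save_report(res, r1, seed = 11, config_path = cfgp)
  save_report(res, r2, seed = 11, config_path = cfgp)
  expect_identical(readLines(r1), readLines(r2))
  j <- jsonlite::fromJSON(r1)
  expect_equal(j$provenance$seed, 11)
  expect_equal(j$results$isppa_w_cm2, res$isppa_w_cm2)
})

test_that("beam-profile CSV round-trips with normalization", {
  path <- withr::local_tempfile(fileext = ".csv")
  z <- seq(3, 7, by = 0.05)
  amp <- exp(-(z - 5)^2)
  write_profile_csv(z, amp, "axial", path)
  back <- read_profile_csv(path)
  expect_equal(max(back$amplitude), 1)
  expect_equal(back$coordinate, z)
  expect_equal(back$amplitude, amp / max(amp))
  expect_true(all(back$axis == "axial"))
})

test_that("media presets match the treatment-simulation table", {
  m <- media_presets()
  expect_equal(m$tumor$density_kg_m3, 1060)
  expect_equal(m$tumor$sound_speed_m_s, 1521)
  expect_equal(m$tumor$attenuation_np_mm, 0.321)
  expect_equal(m$skin$sound_speed_m_s, 1558)
  expect_equal(m$skin$attenuation_np_mm, 1.091)
  expect_equal(m$gel$sound_speed_m_s, 1480)
  expect_equal(m$gel$attenuation_np_mm, 0.110)
  expect_error(medium_preset("bone"), "unknown")
  # user copies never mutate the shipped presets
  g <- medium_preset("gel")
  g$attenuation_np_mm <- 99
  expect_equal(medium_preset("gel")$attenuation_np_mm, 0.110)
})
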