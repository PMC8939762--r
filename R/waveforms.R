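#' Synthesise a pulsed tone-burst waveform
#'
#' Reproducible hydrophone-style fixture: bursts of `n_cycles` sine
#' cycles at the carrier frequency, repeated at the pulse repetition
#' frequency, with optional additive Gaussian noise.  With the default
#' drive (60 cycles of 20.7 MHz) each burst lasts 2.9 us.
#'
#' @param frequency_hz carrier frequency, Hz.
#' @param n_cycles cycles per burst.
#' @param amplitude burst amplitude (arbitrary units, e.g. Pa).
#' @param prf_hz pulse repetition frequency, Hz.
#' @param n_bursts number of repetitions to synthesise.
#' @param duration_s total record length; default `n_bursts / prf_hz`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param sample_rate_hz sampling rate; must be at least `10 *
#'   frequency_hz` (refused otherwise).
#' @param seed optional integer; when given the record is reproducible
#'   and the caller's RNG state is left untouched.
#' @return an `sfat_waveform`: list with `t_s`, `x`, `sample_rate_hz`,
#'   `frequency_hz`.
#' @export
synth_pulsed_waveform <- function(frequency_hz, n_cycles = 60,
                                  amplitude = 1, prf_hz = 60,
                                  n_bursts = 1, duration_s = NULL,
                                  noise_sd = 0,
                                  sample_rate_hz = 16 * frequency_hz,
                                  seed = NULL) {
  if (sample_rate_hz < 10 * frequency_hz) {
    stop(sprintf(
      "sample rate %.3g Hz undersamples the %.3g Hz carrier (need >= 10x)",
      sample_rate_hz, frequency_hz), call. = FALSE)
  }
  if (is.null(duration_s)) duration_s <- n_bursts / prf_hz
  burst_s <- n_cycles / frequency_hz
  if (burst_s > 1 / prf_hz) {
    stop("burst longer than the repetition period", call. = FALSE)
  }
  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  gate <- (t %% (1 / prf_hz)) < burst_s & t < n_bursts / prf_hz
  x <- amplitude * sin(2 * pi * frequency_hz * t) * gate
  if (noise_sd > 0) {
    x <- x + .with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  }
  structure(list(t_s = t, x = x, sample_rate_hz = sample_rate_hz,
                 frequency_hz = frequency_hz),
            class = "sfat_waveform")
}

# evaluate `expr` under a temporary seed, restoring the caller's RNG
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Magnitude spectrum of a waveform
#'
#' One-sided FFT magnitude spectrum with the dominant peak identified.
#' The record is zero-padded to the next highly composite length (which
#' keeps the mixed-radix FFT fast for any record length); the padded
#' length is exposed as attribute `n_fft`.
#'
#' @param wave an [synth_pulsed_waveform()] record (or any
#'   `sfat_waveform`).
#' @return data.frame with `frequency_hz`, `magnitude`; attributes
#'   `peak_hz` (dominant frequency) and `n_fft` (padded length).
#' @export
waveform_spectrum <- function(wave) {
  stopifnot(inherits(wave, "sfat_waveform"))
  n <- stats::nextn(length(wave$x))
  x <- c(wave$x, numeric(n - length(wave$x)))
  sp <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1)
  freq <- (half - 1) * wave$sample_rate_hz / n
  mag <- Mod(sp[half]) / n
  out <- data.frame(frequency_hz = freq, magnitude = mag)
  attr(out, "peak_hz") <- freq[which.max(mag[-1]) + 1]  # skip DC
  attr(out, "n_fft") <- n
  out
}

#' Dominant spectral frequency
#'
#' @param wave an `sfat_waveform`.
#' @return frequency of the largest non-DC spectral magnitude, Hz.
#' @export
dominant_frequency <- function(wave) {
  attr(waveform_spectrum(wave), "peak_hz")
}

#' Linear pressure-voltage calibration fit
#'
#' Least-squares line through (drive voltage, focal pressure) pairs, as
#' measured in a hydrophone voltage sweep.
#'
#' @param voltage_vpp drive voltages (peak-to-peak), V.
#' @param pressure_mpa measured focal pressures, MPa.
#' @return list with `slope` (MPa/V), `intercept` (MPa), `residuals`,
#'   `predict` (function of voltage).
#' @export
pressure_voltage_fit <- function(voltage_vpp, pressure_mpa) {
  if (length(voltage_vpp) < 2 || length(voltage_vpp) != length(pressure_mpa)) {
    stop("need at least two (voltage, pressure) pairs", call. = FALSE)
  }
  if (diff(range(voltage_vpp)) == 0) {
    stop("degenerate fit: all voltages identical", call. = FALSE)
  }
  fit <- stats::lm(pressure_mpa ~ voltage_vpp)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       residuals = unname(stats::residuals(fit)),
       predict = function(v) unname(co[1] + co[2] * v))
}

#' Estimate a time delay between two waveforms by cross-correlation
#'
#' Sub-sample delay of `delayed` relative to `reference` from the
#' cross-correlation peak, refined by parabolic interpolation.  A
#' positive result means `delayed` arrives later.
#'
#' @param reference,delayed numeric vectors sampled at the same rate.
#' @param sample_rate_hz sampling rate, Hz.
#' @return delay in seconds.
#' @export
estimate_delay <- function(reference, delayed, sample_rate_hz) {
  n <- max(length(reference), length(delayed))
  n_pad <- stats::nextn(2 * n)
  a <- c(reference, numeric(n_pad - length(reference)))
  b <- c(delayed, numeric(n_pad - length(delayed)))
  # circular cross-correlation via FFT on zero-padded records
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  idx <- seq_len(n_pad)
  lags <- ifelse(idx <= n_pad / 2, idx - 1, idx - 1 - n_pad)
  i <- which.max(cc)
  shift <- 0
  if (i > 1 && i < length(cc)) {
    y0 <- cc[i - 1]; y1 <- cc[i]; y2 <- cc[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den != 0) shift <- 0.5 * (y0 - y2) / den
  }
  (lags[i] + shift) / sample_rate_hz
}

#' Apply a forward attenuation model to a waveform
#'
#' Scales the record by `exp(-alpha * thickness)`, the amplitude loss of
#' a through-transmission path; forward model for the insertion-loss
#' estimator round trip.
#'
#' @param wave an `sfat_waveform`.
#' @param alpha_np_mm attenuation, Np/mm.
#' @param thickness_mm propagation distance in the sample, mm.
#' @return attenuated `sfat_waveform`.
#' @export
apply_attenuation <- function(wave, alpha_np_mm, thickness_mm) {
  stopifnot(inherits(wave, "sfat_waveform"))
  wave$x <- wave$x * exp(-alpha_np_mm * thickness_mm)
  wave
}

#' Delay a waveform by a fractional number of samples
#'
#' Exact (spectral) delay used as the forward model for time-of-flight
#' round trips.
#'
#' @param wave an `sfat_waveform`.
#' @param delay_s delay to apply, s (positive delays shift later).
#' @return delayed `sfat_waveform`.
#' @export
delay_waveform <- function(wave, delay_s) {
  stopifnot(inherits(wave, "sfat_waveform"))
  n <- length(wave$x)
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) * wave$sample_rate_hz / n
  wave$x <- Re(stats::fft(stats::fft(wave$x) * exp(-2i * pi * f * delay_s),
                          inverse = TRUE)) / n
  wave
}
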