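#' Pulsed-drive parameters
#'
#' @param prf_hz pulse repetition frequency, Hz.
#' @param pulse_width_s pulse width, s.
#' @param drive_vpp optional peak-to-peak drive voltage, V.
#' @return an `sfat_pulse` with the derived `duty_cycle = prf * width`.
#' @examples
#' pulse_params(60, 1.45e-3)$duty_cycle  # 0.087
#' @export
pulse_params <- function(prf_hz = 60, pulse_width_s = 1.45e-3,
                         drive_vpp = NULL) {
  if (prf_hz <= 0 || pulse_width_s <= 0) {
    stop("PRF and pulse width must be positive", call. = FALSE)
  }
  dc <- prf_hz * pulse_width_s
  if (dc > 1) {
    stop(sprintf("duty cycle %.3g exceeds 1 (pulses overlap)", dc),
         call. = FALSE)
  }
  structure(list(prf_hz = prf_hz, pulse_width_s = pulse_width_s,
                 duty_cycle = dc, drive_vpp = drive_vpp),
            class = "sfat_pulse")
}

#' Spatial-peak pulse-average intensity
#'
#' Plane-wave relation `I = p^2 / (2 rho c)`, converted to W/cm^2.
#' `p` is the pressure amplitude at the spatial peak.
#'
#' @param pressure_pa pressure amplitude, Pa.
#' @param med an [medium()] object, or `NULL` when `density_kg_m3` and
#'   `sound_speed_m_s` are given directly.
#' @param density_kg_m3,sound_speed_m_s medium properties, used when
#'   `med` is `NULL`.
#' @return intensity in W/cm^2.
#' @examples
#' isppa(4.53e6, medium_preset("water"))   # ~693 W/cm^2
#' isppa(3.0e6, medium_preset("tumor"))    # ~279 W/cm^2
#' @export
isppa <- function(pressure_pa, med = NULL, density_kg_m3 = NULL,
                  sound_speed_m_s = NULL) {
  if (!is.null(med)) {
    stopifnot(inherits(med, "sfat_medium"))
    density_kg_m3 <- med$density_kg_m3
    sound_speed_m_s <- med$sound_speed_m_s
  }
  if (pressure_pa < 0 || density_kg_m3 <= 0 || sound_speed_m_s <= 0) {
    stop("pressure must be non-negative and medium properties positive",
         call. = FALSE)
  }
  pressure_pa^2 / (2 * density_kg_m3 * sound_speed_m_s) / 1e4
}

#' Spatial-peak temporal-average intensity
#'
#' `I_SPTA = I_SPPA * duty_cycle`.
#'
#' @param isppa_w_cm2 pulse-average intensity, W/cm^2.
#' @param pulse an [pulse_params()] object.
#' @return intensity in W/cm^2.
#' @export
ispta <- function(isppa_w_cm2, pulse) {
  stopifnot(inherits(pulse, "sfat_pulse"))
  if (isppa_w_cm2 < 0) stop("intensity must be non-negative", call. = FALSE)
  isppa_w_cm2 * pulse$duty_cycle
}

#' Mechanical index
#'
#' Peak negative pressure in MPa divided by the square root of the
#' frequency in MHz; a proxy for inertial-cavitation risk.
#'
#' @param p_neg_mpa peak negative (rarefactional) pressure, MPa.
#' @param frequency_mhz frequency, MHz.
#' @return dimensionless MI.
#' @examples
#' mechanical_index(3.0, 20.7)  # ~0.66
#' @export
mechanical_index <- function(p_neg_mpa, frequency_mhz) {
  if (frequency_mhz <= 0) stop("frequency must be positive", call. = FALSE)
  p_neg_mpa / sqrt(frequency_mhz)
}

#' Temperature-time record
#'
#' @param time_min sampling times, minutes, strictly increasing.
#' @param temp_c temperatures, degrees C.
#' @return an `sfat_thermal_record`.
#' @export
thermal_record <- function(time_min, temp_c) {
  if (length(time_min) != length(temp_c) || length(time_min) < 1) {
    stop("time and temperature must be non-empty and equal length",
         call. = FALSE)
  }
  if (length(time_min) > 1 && any(diff(time_min) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(time_min = as.numeric(time_min),
                 temp_c = as.numeric(temp_c)),
            class = "sfat_thermal_record")
}

# Sapareto-Dewey rate constants: each degree above 43 C doubles the
# effective time, each degree below quarters it.
.cem43_R <- function(temp_c) ifelse(temp_c >= 43, 0.5, 0.25)

#' Cumulative equivalent minutes at 43 degrees C
#'
#' Thermal dose `sum(dt_i * R^(43 - T_i))` with the piecewise rate
#' constant R = 0.5 at or above 43 C and 0.25 below.  Each interval uses
#' the mean of its endpoint temperatures.
#'
#' @param record an [thermal_record()].
#' @return equivalent minutes at 43 C.
#' @seealso [cem43_const()] for a constant-temperature exposure.
#' @export
cem43 <- function(record) {
  stopifnot(inherits(record, "sfat_thermal_record"))
  if (length(record$time_min) < 2) return(0)
  dt <- diff(record$time_min)
  tm <- (record$temp_c[-1] + record$temp_c[-length(record$temp_c)]) / 2
  sum(dt * .cem43_R(tm)^(43 - tm))
}

#' @rdname cem43
#' @param temp_c constant exposure temperature, degrees C.
#' @param time_min exposure duration, minutes.
#' @examples
#' cem43_const(35.6, 11.5) * 60 * 1000  # ~24 ms
#' @export
cem43_const <- function(temp_c, time_min) {
  if (time_min < 0) stop("exposure time must be non-negative", call. = FALSE)
  time_min * .cem43_R(temp_c)^(43 - temp_c)
}

#' Assemble dose metrics for a treatment pressure
#'
#' @param pressure_mpa peak pressure amplitude in tissue, MPa (taken
#'   equal to the peak negative pressure under the linear model).
#' @param med tissue [medium()].
#' @param pulse an [pulse_params()].
#' @param frequency_hz operating frequency, Hz.
#' @param cem43_min optional thermal dose to carry along, minutes.
#' @return an `sfat_dose_metrics` list: `peak_pressure_mpa`,
#'   `isppa_w_cm2`, `ispta_w_cm2`, `mi`, `duty_cycle`, `cem43_min`.
#' @export
dose_metrics <- function(pressure_mpa, med, pulse, frequency_hz = 20.7e6,
                         cem43_min = NA_real_) {
  ip <- isppa(pressure_mpa * 1e6, med)
  structure(
    list(peak_pressure_mpa = pressure_mpa,
         isppa_w_cm2 = ip,
         ispta_w_cm2 = ispta(ip, pulse),
         mi = mechanical_index(pressure_mpa, frequency_hz / 1e6),
         duty_cycle = pulse$duty_cycle,
         cem43_min = cem43_min),
    class = "sfat_dose_metrics")
}

#' @export
print.sfat_dose_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("dose metrics: p = %.3g MPa, I_SPPA = %.1f W/cm^2, ",
           "I_SPTA = %.1f W/cm^2, MI = %.2f\n"),
    x$peak_pressure_mpa, x$isppa_w_cm2, x$ispta_w_cm2, x$mi))
  if (!is.na(x$cem43_min)) cat(sprintf("  CEM43 = %.3g min\n", x$cem43_min))
  invisible(x)
}

#' Compare dose metrics against diagnostic safety limits
#'
#' Strict-less comparison against configurable limits (defaults: the FDA
#' diagnostic-ultrasound track-1 limits I_SPPA < 190 W/cm^2, I_SPTA <
#' 0.720 W/cm^2, MI < 1.9).  A value exactly at a limit fails.  Each row
#' also carries a qualitative category relative to the limit: `"close"`
#' (within a factor of 2 either side), `"higher"` or `"lower"`.
#'
#' @param metrics an [dose_metrics()] object.
#' @param limits named numeric vector with elements `isppa_w_cm2`,
#'   `ispta_w_cm2`, `mi`.
#' @return data.frame with columns `quantity`, `value`, `limit`, `pass`,
#'   `category`.
#' @export
safety_report <- function(metrics,
                          limits = c(isppa_w_cm2 = 190,
                                     ispta_w_cm2 = 0.720,
                                     mi = 1.9)) {
  stopifnot(inherits(metrics, "sfat_dose_metrics"))
  vals <- c(isppa_w_cm2 = metrics$isppa_w_cm2,
            ispta_w_cm2 = metrics$ispta_w_cm2,
            mi = metrics$mi)
  limits <- limits[names(vals)]
  ratio <- vals / limits
  category <- ifelse(ratio >= 0.5 & ratio <= 2, "close",
                     ifelse(ratio > 2, "higher", "lower"))
  data.frame(quantity = names(vals),
             value = unname(vals),
             limit = unname(limits),
             pass = unname(vals < limits),
             category = unname(category),
             row.names = NULL)
}

#' Attenuation from a substitution insertion-loss measurement
#'
#' With a through-transmission path measured once through the reference
#' medium and once with a sample of known thickness inserted,
#' `alpha_sample = alpha_ref + ln(A_ref / A_sample) / thickness`.
#'
#' @param amp_reference amplitude without the sample (any consistent unit).
#' @param amp_through_sample amplitude with the sample inserted.
#' @param thickness_mm sample thickness, mm.
#' @param alpha_reference_np_mm attenuation of the reference medium, Np/mm.
#' @return sample attenuation, Np/mm.
#' @export
attenuation_from_insertion_loss <- function(amp_reference,
                                            amp_through_sample,
                                            thickness_mm,
                                            alpha_reference_np_mm = 0) {
  if (amp_reference <= 0 || amp_through_sample <= 0) {
    stop("amplitudes must be positive", call. = FALSE)
  }
  if (thickness_mm <= 0) stop("thickness must be positive", call. = FALSE)
  alpha_reference_np_mm + log(amp_reference / amp_through_sample) / thickness_mm
}

#' Sound speed from a substitution time-of-flight measurement
#'
#' Replacing a thickness `d` of reference medium by the sample changes
#' the arrival time by `dt = d/c_ref - d/c_sample` (an early arrival,
#' positive `dt`, means a faster sample), so
#' `1/c_sample = 1/c_ref - dt/d`.
#'
#' @param dt_s arrival-time advance caused by the sample, s.
#' @param thickness_mm sample thickness, mm.
#' @param c_reference_m_s reference sound speed, m/s.
#' @return sample sound speed, m/s.
#' @export
sound_speed_from_tof <- function(dt_s, thickness_mm, c_reference_m_s) {
  if (thickness_mm <= 0 || c_reference_m_s <= 0) {
    stop("thickness and reference speed must be positive", call. = FALSE)
  }
  inv <- 1 / c_reference_m_s - dt_s / (thickness_mm / 1000)
  if (inv <= 0) {
    stop("measured delay implies a non-physical (non-positive) sound speed",
         call. = FALSE)
  }
  1 / inv
}
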