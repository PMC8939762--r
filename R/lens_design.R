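#' Fresnel half-wavelength-band boundary radii
#'
#' Radii at which the path length to the design focal point (on the axis,
#' `focal_length_mm` above the aperture centre) exceeds the focal length
#' by successive half wavelengths:
#' `sqrt(r_n^2 + F^2) = F + n*lambda/2`, i.e.
#' `r_n = sqrt(n*lambda*F + (n*lambda/2)^2)`.
#' Annular zones between consecutive boundaries contribute alternately
#' constructively and destructively at the focus; blocking the
#' destructive zones (with air cavities) yields a focusing lens.
#'
#' @param focal_length_mm design focal length F in mm.
#' @param wavelength_mm acoustic wavelength lambda in the coupling medium, mm.
#' @param n_boundaries number of boundaries to return (n = 1..N).
#' @return numeric vector of radii in mm, strictly ascending.
#' @examples
#' # 5 mm focus at 20.7 MHz in water: first boundary ~595 um
#' fhwb_boundary_radii(5, 1465 / 20.7e6 * 1000, 11)[1] * 1000
#' @export
fhwb_boundary_radii <- function(focal_length_mm, wavelength_mm, n_boundaries) {
  if (!is.numeric(focal_length_mm) || focal_length_mm <= 0 ||
      !is.numeric(wavelength_mm) || wavelength_mm <= 0) {
    stop("focal length and wavelength must be positive", call. = FALSE)
  }
  if (n_boundaries < 1) stop("n_boundaries must be >= 1", call. = FALSE)
  n <- seq_len(n_boundaries)
  sqrt(n * wavelength_mm * focal_length_mm + (n * wavelength_mm / 2)^2)
}

#' Transmitting annuli from band boundaries
#'
#' Pairs up the boundary radii into the non-air-cavity (transmitting)
#' regions: the central disc `(0, r1)` then rings `(r2, r3)`, `(r4, r5)`,
#' ...  The gaps between consecutive annuli are the blocked air-cavity
#' rings.  A trailing unpaired boundary (odd count beyond the first) is
#' dropped, as the corresponding zone would be blocked.
#'
#' @param radii ascending boundary radii (mm), as from
#'   [fhwb_boundary_radii()].
#' @return numeric matrix with columns `inner`, `outer` (mm), one row per
#'   transmitting annulus.
#' @export
transmit_annuli <- function(radii) {
  if (length(radii) < 1) stop("need at least one boundary radius", call. = FALSE)
  if (any(diff(radii) <= 0) || any(radii <= 0)) {
    stop("boundary radii must be positive and strictly increasing",
         call. = FALSE)
  }
  b <- c(0, radii)
  n_pairs <- length(b) %/% 2L
  m <- matrix(b[seq_len(2L * n_pairs)], ncol = 2, byrow = TRUE)
  colnames(m) <- c("inner", "outer")
  m
}

#' Quarter-wavelength matching-layer thickness
#'
#' Thickness `c/(4f)` of a coating that maximises transmission between
#' two mismatched media (e.g. the Parylene seal over the transducer).
#'
#' @param sound_speed_m_s sound speed in the layer material, m/s.
#' @param frequency_hz operating frequency, Hz.
#' @return thickness in mm.
#' @export
quarter_wave_thickness <- function(sound_speed_m_s, frequency_hz) {
  if (sound_speed_m_s <= 0 || frequency_hz <= 0) {
    stop("sound speed and frequency must be positive", call. = FALSE)
  }
  sound_speed_m_s * 1000 / (4 * frequency_hz)
}

#' Odd-harmonic thickness-mode resonance frequency
#'
#' A piezoelectric plate of thickness `t` resonates in thickness mode at
#' odd multiples of its fundamental: `f = n * c / (2 t)` with `n` odd.
#' Thick substrates driven at a high odd harmonic (e.g. the 9th) trade
#' coupling efficiency for mechanical sturdiness.
#'
#' @param thickness_mm plate thickness, mm.
#' @param harmonic odd harmonic order (1, 3, 5, ...).
#' @param sound_speed_m_s longitudinal sound speed in the plate, m/s.
#' @return resonance frequency in Hz.
#' @export
harmonic_frequency <- function(thickness_mm, harmonic, sound_speed_m_s) {
  if (thickness_mm <= 0 || sound_speed_m_s <= 0) {
    stop("thickness and sound speed must be positive", call. = FALSE)
  }
  if (harmonic < 1 || harmonic %% 2 == 0) {
    stop("harmonic order must be a positive odd integer", call. = FALSE)
  }
  harmonic * sound_speed_m_s * 1000 / (2 * thickness_mm)
}

#' Design a Fresnel air-cavity lens
#'
#' Complete lens description: band boundaries, transmitting annuli and
#' quarter-wave matching-layer thickness for a given focal length and
#' operating frequency.  The default design sound speed of 1465 m/s is
#' the water value that best reproduces the reference device's printed
#' boundary radii (within 3 um); it is configurable for other coupling
#' media or temperatures.
#'
#' @param focal_length_mm design focal length, mm.
#' @param frequency_hz operating frequency, Hz.
#' @param design_sound_speed_m_s sound speed used for the wavelength, m/s.
#' @param n_boundaries number of band boundaries (11 gives six
#'   transmitting regions).
#' @param matching_layer_sound_speed_m_s sound speed of the sealing layer
#'   (default: Parylene, back-computed from the reference 26 um quarter
#'   wave at 20.7 MHz), used for the matching-layer thickness.
#' @return an object of class `sfat_lens` with elements
#'   `focal_length_mm`, `frequency_hz`, `design_sound_speed_m_s`,
#'   `wavelength_mm`, `boundary_radii_mm`, `annuli_mm` (matrix),
#'   `matching_layer_mm`.
#' @examples
#' lens <- lens_design()
#' lens
#' @export
lens_design <- function(focal_length_mm = 5,
                        frequency_hz = 20.7e6,
                        design_sound_speed_m_s = 1465,
                        n_boundaries = 11,
                        matching_layer_sound_speed_m_s = 2153) {
  wavelength_mm <- design_sound_speed_m_s * 1000 / frequency_hz
  radii <- fhwb_boundary_radii(focal_length_mm, wavelength_mm, n_boundaries)
  structure(
    list(focal_length_mm = focal_length_mm,
         frequency_hz = frequency_hz,
         design_sound_speed_m_s = design_sound_speed_m_s,
         wavelength_mm = wavelength_mm,
         boundary_radii_mm = radii,
         annuli_mm = transmit_annuli(radii),
         matching_layer_mm = quarter_wave_thickness(
           matching_layer_sound_speed_m_s, frequency_hz)),
    class = "sfat_lens")
}

#' @export
print.sfat_lens <- function(x, ...) {
  cat("Fresnel air-cavity lens design\n")
  cat(sprintf("  focal length     : %g mm\n", x$focal_length_mm))
  cat(sprintf("  frequency        : %g MHz\n", x$frequency_hz / 1e6))
  cat(sprintf("  design c         : %g m/s (lambda = %.2f um)\n",
              x$design_sound_speed_m_s, x$wavelength_mm * 1000))
  cat(sprintf("  matching layer   : %.1f um (quarter wave)\n",
              x$matching_layer_mm * 1000))
  cat("  transmitting annuli (inner, outer um):\n")
  ann <- round(x$annuli_mm * 1000)
  lab <- c("1st circle", paste0(c("2nd", "3rd", paste0(4:9, "th"))[
    seq_len(max(0, nrow(ann) - 1))], " ring"))
  for (i in seq_len(nrow(ann))) {
    cat(sprintf("    %-10s %5d, %5d\n", lab[i], ann[i, 1], ann[i, 2]))
  }
  invisible(x)
}

# internal: accept either a lens object or an annuli matrix
.as_annuli <- function(x) {
  if (inherits(x, "sfat_lens")) return(x$annuli_mm)
  if (is.matrix(x) && ncol(x) == 2) {
    m <- x
    colnames(m) <- c("inner", "outer")
    return(m)
  }
  stop("expected an 'sfat_lens' or a 2-column annuli matrix", call. = FALSE)
}
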