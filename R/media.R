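#' Acoustic medium description
#'
#' Bundles the three material properties that govern linear acoustic
#' propagation at a fixed frequency: mass density, sound speed and
#' amplitude attenuation.
#'
#' @param name character label (e.g. `"tumor"`).
#' @param density_kg_m3 mass density in kg/m^3.
#' @param sound_speed_m_s longitudinal sound speed in m/s.
#' @param attenuation_np_mm amplitude attenuation coefficient in Np/mm
#'   (nepers per millimetre) at the operating frequency.
#' @return an object of class `sfat_medium`.
#' @examples
#' medium("water", 1000, 1480, 0)
#' @export
medium <- function(name, density_kg_m3, sound_speed_m_s, attenuation_np_mm) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density_kg_m3) || density_kg_m3 <= 0 ||
      !is.numeric(sound_speed_m_s) || sound_speed_m_s <= 0 ||
      !is.numeric(attenuation_np_mm) || attenuation_np_mm < 0) {
    stop("medium properties must be positive (attenuation may be zero)",
         call. = FALSE)
  }
  structure(
    list(name = name,
         density_kg_m3 = as.numeric(density_kg_m3),
         sound_speed_m_s = as.numeric(sound_speed_m_s),
         attenuation_np_mm = as.numeric(attenuation_np_mm)),
    class = "sfat_medium")
}

#' @export
print.sfat_medium <- function(x, ...) {
  cat(sprintf("<medium '%s': rho = %g kg/m^3, c = %g m/s, alpha = %g Np/mm>\n",
              x$name, x$density_kg_m3, x$sound_speed_m_s, x$attenuation_np_mm))
  invisible(x)
}

# preset cache, filled on first access
.preset_env <- new.env(parent = emptyenv())

#' Built-in material presets
#'
#' Reads the versioned preset file shipped with the package
#' (`extdata/media_presets.yaml`) containing the gel, mouse-skin and
#' B16F10-tumor properties used throughout the treatment simulations,
#' plus lossless water for oracle checks.  User code receives fresh
#' copies; presets themselves are never mutated.
#'
#' @return named list of [medium()] objects.
#' @export
media_presets <- function() {
  if (is.null(.preset_env$media)) {
    path <- system.file("extdata", "media_presets.yaml", package = "sfat")
    raw <- yaml::read_yaml(path)
    .preset_env$media <- lapply(names(raw$media), function(nm) {
      m <- raw$media[[nm]]
      medium(nm, m$density_kg_m3, m$sound_speed_m_s, m$attenuation_np_mm)
    })
    names(.preset_env$media) <- names(raw$media)
  }
  .preset_env$media
}

#' Look up a single material preset by name
#'
#' @param name one of `"gel"`, `"skin"`, `"tumor"`, `"water"`.
#' @return an `sfat_medium`.
#' @export
medium_preset <- function(name) {
  m <- media_presets()
  if (!name %in% names(m)) {
    stop(sprintf("unknown medium preset '%s' (available: %s)", name,
                 paste(names(m), collapse = ", ")), call. = FALSE)
  }
  m[[name]]
}

#' Complex acoustic wavenumber of a medium
#'
#' `k = 2*pi*f/c + i*alpha` in units of 1/mm; the imaginary part encodes
#' amplitude decay `exp(-alpha * distance)`.
#'
#' @param med an [medium()] object.
#' @param frequency_hz operating frequency in Hz.
#' @return complex scalar, rad/mm (real part) and Np/mm (imaginary part).
#' @export
wavenumber <- function(med, frequency_hz) {
  stopifnot(inherits(med, "sfat_medium"), frequency_hz > 0)
  2 * pi * frequency_hz / (med$sound_speed_m_s * 1000) +
    1i * med$attenuation_np_mm
}
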