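#' @title Axisymmetric scalar-diffraction field simulation
#' @description Internal engine plus user-facing propagation wrappers.
#'   The source is a uniformly vibrating piston over the transmitting
#'   annuli of the lens (blocked rings radiate nothing); propagation is
#'   linear scalar acoustics.  Two routes are provided: a
#'   Hankel-transform angular-spectrum method (default; exact for planar
#'   layered media, fast) and a direct Rayleigh-Sommerfeld first
#'   integral (homogeneous media only, used for cross-checks).
#' @name field_sim
NULL

# Hankel spectrum of the aperture velocity distribution: uniform over the
# transmitting annuli.  H0{1(a<r<b)}(kr) = (b J1(kr b) - a J1(kr a))/kr.
.aperture_spectrum <- function(kr, annuli) {
  out <- numeric(length(kr))
  zero <- kr == 0
  for (i in seq_len(nrow(annuli))) {
    a <- annuli[i, 1]
    b <- annuli[i, 2]
    if (any(!zero)) {
      t1 <- if (a > 0) a * besselJ(kr[!zero] * a, 1) else 0
      out[!zero] <- out[!zero] + (b * besselJ(kr[!zero] * b, 1) - t1) / kr[!zero]
    }
    out[zero] <- out[zero] + (b^2 - a^2) / 2
  }
  out
}

# principal square root with Im >= 0 (decaying evanescent branch)
.kz_branch <- function(k2, kr) {
  kz <- sqrt(k2 - kr^2)
  flip <- Im(kz) < 0
  kz[flip] <- -kz[flip]
  kz
}

# Angular-spectrum propagation through contiguous planar layers.
#
# annuli: 2-col matrix (mm); k_layers: complex wavenumbers per layer
# (1/mm); thickness_mm: thicknesses of all but the last (semi-infinite)
# layer; r, z: output grids (mm, z >= 0 from the source plane).
# Returns list(p, vz): complex matrices [length(r) x length(z)] of
# pressure and (optionally) axial particle velocity, both per unit
# source amplitude (a lossless piston peaks at 2 on axis).
#
# Propagating part uses kr = Re(k1) sin(theta) (removes the 1/kz source
# singularity); the evanescent tail kr = Re(k1) cosh(u) matters within a
# few aperture radii of the source and is integrated explicitly.
.asm_field <- function(annuli, k_layers, thickness_mm, r, z,
                       n_theta = 6000, n_evanescent = 300, u_max = 1.2,
                       velocity = FALSE) {
  stopifnot(length(k_layers) == length(thickness_mm) + 1L, all(z >= 0))
  k1 <- k_layers[1]
  kt <- Re(k1)
  nl <- length(k_layers)

  # per-layer path length for each field depth z
  tops <- cumsum(c(0, thickness_mm))
  D <- matrix(0, nl, length(z))
  for (l in seq_len(nl)) {
    hi <- if (l < nl) tops[l + 1] else Inf
    D[l, ] <- pmax(0, pmin(z, hi) - tops[l])
  }

  field_part <- function(kr, w_src, kz1) {
    # w_src already contains aperture spectrum, jacobian and quadrature
    # weight; kz1 is the first-layer axial wavenumber on this segment.
    KZ <- vapply(seq_len(nl), function(l) .kz_branch(k_layers[l]^2, kr),
                 complex(length(kr)))
    if (is.null(dim(KZ))) KZ <- matrix(KZ, nrow = length(kr))
    E <- exp(1i * (KZ %*% D))
    J0 <- outer(kr, r, function(kk, rr) besselJ(kk * rr, 0))
    if (length(r) && any(r == 0)) J0[, r == 0] <- 1
    p <- crossprod(J0, (k1 / kz1) * w_src * E)
    v <- if (velocity) crossprod(J0, (kz1 / k1) * (k1 / kz1) * w_src * E)
         else NULL
    list(p = p, v = v)
  }

  # propagating segment (midpoint rule in theta)
  dth <- (pi / 2) / n_theta
  th <- seq(dth / 2, pi / 2 - dth / 2, length.out = n_theta)
  kr_p <- kt * sin(th)
  w_p <- .aperture_spectrum(kr_p, annuli) * kr_p * kt * cos(th) * dth
  kz1_p <- .kz_branch(k1^2, kr_p)
  prop <- field_part(kr_p, w_p, kz1_p)

  # evanescent segment
  if (n_evanescent > 0) {
    du <- u_max / n_evanescent
    u <- seq(du / 2, u_max - du / 2, length.out = n_evanescent)
    kr_e <- kt * cosh(u)
    w_e <- .aperture_spectrum(kr_e, annuli) * kr_e * kt * sinh(u) * du
    kz1_e <- .kz_branch(k1^2, kr_e)
    evan <- field_part(kr_e, w_e, kz1_e)
    prop$p <- prop$p + evan$p
    if (velocity) prop$v <- prop$v + evan$v
  }
  prop
}

# Direct Rayleigh-Sommerfeld first integral (homogeneous medium):
# p(r, z) = (-i k / 2 pi) Int_S exp(i k R) / R dS over the annuli, per
# unit source amplitude.  Quadrature in source radius and azimuth;
# intended for small numbers of field points.
.rs_field <- function(annuli, k, r, z, dr_src = NULL) {
  lam <- 2 * pi / Re(k)
  if (is.null(dr_src)) dr_src <- lam / 10
  p <- matrix(0 + 0i, length(r), length(z))
  for (i in seq_len(nrow(annuli))) {
    a <- annuli[i, 1]; b <- annuli[i, 2]
    n_src <- max(8L, ceiling((b - a) / dr_src))
    rs <- a + (seq_len(n_src) - 0.5) * (b - a) / n_src
    w_r <- rs * (b - a) / n_src
    for (ir in seq_along(r)) {
      rr <- r[ir]
      for (is in seq_along(rs)) {
        # azimuthal phase span ~ k * 2 r r' / R_min sets the sample count
        rmin2 <- min(z)^2 + (rr - rs[is])^2
        n_phi <- max(16L, 8L * ceiling(Re(k) * 2 * rr * rs[is] /
                                         (2 * pi * sqrt(rmin2)) * 2 * pi + 1))
        phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
        for (iz in seq_along(z)) {
          R <- sqrt(z[iz]^2 + rr^2 + rs[is]^2 - 2 * rr * rs[is] * cos(phi))
          p[ir, iz] <- p[ir, iz] +
            w_r[is] * sum(exp(1i * k * R) / R) * (2 * pi / n_phi)
        }
      }
    }
  }
  p * (-1i * k / (2 * pi))
}

#' Closed-form on-axis field of a lossless circular piston
#'
#' Exact on-axis pressure amplitude of a uniformly vibrating disc of
#' radius `a` in a lossless medium:
#' `2 * |sin((k/2) * (sqrt(a^2 + z^2) - z))|` per unit source amplitude.
#' Serves as an independent oracle for the numerical propagators.
#'
#' @param a_mm piston radius, mm.
#' @param k_per_mm real wavenumber `2*pi/lambda`, 1/mm.
#' @param z_mm axial distances (>= 0), mm.
#' @return amplitude vector (dimensionless, source-normalized).
#' @export
on_axis_piston_closed_form <- function(a_mm, k_per_mm, z_mm) {
  stopifnot(a_mm >= 0, k_per_mm > 0, all(z_mm >= 0))
  2 * abs(sin(k_per_mm / 2 * (sqrt(a_mm^2 + z_mm^2) - z_mm)))
}

#' Propagate the lens field in a homogeneous medium
#'
#' Pressure field of the masked aperture (uniform velocity over the
#' transmitting annuli, zero over blocked rings) in a single medium.
#'
#' @param lens an [lens_design()] object or 2-column annuli matrix (mm).
#' @param med an [medium()] object (attenuation honoured via the complex
#'   wavenumber).
#' @param frequency_hz operating frequency, Hz (default: taken from the
#'   lens).
#' @param r_mm,z_mm output grids, mm.  Defaults: radial 0 to 0.4 mm at
#'   lambda/10, axial 0.5F to 1.5F at 10 um.
#' @param method `"angular_spectrum"` (default) or `"rayleigh"` (direct
#'   integral; slow, homogeneous cross-checks only).
#' @param normalize scale the returned field so the peak amplitude is 1.
#' @param n_theta,n_evanescent,u_max quadrature resolution of the
#'   angular-spectrum engine.
#' @return an `sfat_field`: list with `r_mm`, `z_mm`, complex matrix `p`
#'   (`length(r) x length(z)`), `frequency_hz`, `method`, `media`,
#'   `calibration_scale` (Pa per unit source amplitude; `NA` when
#'   uncalibrated).
#' @details The radial grid must resolve the wavelength: grid steps
#'   coarser than lambda/4 are refused.  An empty annuli matrix yields an
#'   identically zero field with a warning.
#' @export
propagate_homogeneous <- function(lens, med,
                                  frequency_hz = NULL,
                                  r_mm = NULL, z_mm = NULL,
                                  method = c("angular_spectrum", "rayleigh"),
                                  normalize = FALSE,
                                  n_theta = 6000, n_evanescent = 300,
                                  u_max = 1.2) {
  method <- match.arg(method)
  annuli <- .as_annuli_or_empty(lens)
  if (is.null(frequency_hz)) {
    if (!inherits(lens, "sfat_lens")) {
      stop("frequency_hz is required when 'lens' is a bare annuli matrix",
           call. = FALSE)
    }
    frequency_hz <- lens$frequency_hz
  }
  lam <- med$sound_speed_m_s * 1000 / frequency_hz
  F_mm <- if (inherits(lens, "sfat_lens")) lens$focal_length_mm else 5
  if (is.null(r_mm)) r_mm <- seq(0, 0.4, by = lam / 10)
  if (is.null(z_mm)) z_mm <- seq(0.5 * F_mm, 1.5 * F_mm, by = 0.01)
  .check_grid(r_mm, lam)
  .check_grid(z_mm, lam * 4)  # axial sampling need only resolve the envelope

  if (nrow(annuli) == 0) {
    warning("no transmitting annuli: field is identically zero")
    p <- matrix(0 + 0i, length(r_mm), length(z_mm))
  } else if (method == "angular_spectrum") {
    k <- wavenumber(med, frequency_hz)
    p <- .asm_field(annuli, k, numeric(0), r_mm, z_mm,
                    n_theta = n_theta, n_evanescent = n_evanescent,
                    u_max = u_max)$p
  } else {
    k <- wavenumber(med, frequency_hz)
    p <- .rs_field(annuli, k, r_mm, z_mm)
  }
  if (normalize && any(Mod(p) > 0)) p <- p / max(Mod(p))
  structure(
    list(r_mm = r_mm, z_mm = z_mm, p = p, frequency_hz = frequency_hz,
         method = method, media = list(med), layer_thickness_mm = numeric(0),
         calibration_scale = NA_real_),
    class = "sfat_field")
}

.as_annuli_or_empty <- function(x) {
  if (is.matrix(x) && nrow(x) == 0) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("inner", "outer"))))
  }
  .as_annuli(x)
}

.check_grid <- function(g, lam) {
  # dense profile grids must resolve the wavelength; a handful of probe
  # points is allowed (the spectral solution is evaluated pointwise)
  if (length(g) >= 8) {
    step <- stats::median(diff(g))
    if (step > lam / 4 + 1e-12) {
      stop(sprintf(
        "grid step %.4g mm is coarser than lambda/4 = %.4g mm; refine the grid",
        step, lam / 4), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.sfat_field <- function(x, ...) {
  cat(sprintf(
    "<pressure field: %d r x %d z points, method '%s', media: %s%s>\n",
    length(x$r_mm), length(x$z_mm), x$method,
    paste(vapply(x$media, `[[`, "", "name"), collapse = "/"),
    if (is.na(x$calibration_scale)) "" else
      sprintf(", calibrated (%.3g Pa/unit)", x$calibration_scale)))
  invisible(x)
}

#' Layered propagation path
#'
#' Contiguous planar layers from the transducer surface (`z = 0`, +z
#' toward the target): coupling gel over a distance `gel_mm` (the
#' transducer-to-skin standoff), skin of thickness `skin_mm`, then
#' semi-infinite tumor.
#'
#' @param gel_mm transducer-to-skin distance (gel span), mm.
#' @param skin_mm skin thickness, mm.
#' @param media named list with elements `gel`, `skin`, `tumor`
#'   ([medium()] objects); defaults to the built-in presets.
#' @return an object of class `sfat_path`.
#' @export
layered_path <- function(gel_mm, skin_mm, media = media_presets()) {
  if (gel_mm < 0 || skin_mm < 0) {
    stop("layer thicknesses must be non-negative", call. = FALSE)
  }
  structure(
    list(media = list(media$gel, media$skin, media$tumor),
         thickness_mm = c(gel_mm, skin_mm)),
    class = "sfat_path")
}

#' Propagate the lens field through a layered tissue path
#'
#' Each layer contributes phase through its sound speed and amplitude
#' decay through its attenuation (complex wavenumber); interface
#' reflections are neglected (normal-incidence impedance mismatches for
#' gel/skin/tumor are below ~8%, a <=1% amplitude effect).  The absolute
#' pressure scale is set so that the all-gel (free-field) configuration
#' reproduces `calibration_mpa` at its focus; the same source drive is
#' then applied to the layered path.
#'
#' @param lens an [lens_design()] object.
#' @param path an [layered_path()].
#' @param r_mm,z_mm output grids (mm); default axial-only grid spanning
#'   0.6F to 1.5F at 5 um.
#' @param calibration_mpa free-field focal pressure used to scale the
#'   source (default 4.53 MPa, the reference hydrophone value at full
#'   drive).
#' @param n_theta,n_evanescent,u_max quadrature controls.
#' @return an `sfat_field` whose `p` is in MPa.
#' @export
propagate_layered <- function(lens, path,
                              r_mm = 0, z_mm = NULL,
                              calibration_mpa = 4.53,
                              n_theta = 6000, n_evanescent = 300,
                              u_max = 1.2) {
  stopifnot(inherits(lens, "sfat_lens"), inherits(path, "sfat_path"))
  if (calibration_mpa <= 0) stop("calibration must be positive", call. = FALSE)
  F_mm <- lens$focal_length_mm
  if (is.null(z_mm)) z_mm <- seq(0.6 * F_mm, 1.5 * F_mm, by = 0.005)
  k_layers <- vapply(path$media, wavenumber, complex(1),
                     frequency_hz = lens$frequency_hz)
  scale <- calibration_mpa / .free_field_peak(lens, path$media[[1]],
                                              n_theta = n_theta,
                                              n_evanescent = n_evanescent,
                                              u_max = u_max)
  p <- .asm_field(lens$annuli_mm, k_layers, path$thickness_mm, r_mm, z_mm,
                  n_theta = n_theta, n_evanescent = n_evanescent,
                  u_max = u_max)$p * scale
  structure(
    list(r_mm = r_mm, z_mm = z_mm, p = p, frequency_hz = lens$frequency_hz,
         method = "angular_spectrum", media = path$media,
         layer_thickness_mm = path$thickness_mm,
         calibration_scale = scale * 1e6),
    class = "sfat_field")
}

# on-axis peak amplitude (per unit source) in the all-gel configuration
.free_field_peak <- function(lens, gel, n_theta = 6000, n_evanescent = 300,
                             u_max = 1.2) {
  F_mm <- lens$focal_length_mm
  z <- seq(0.7 * F_mm, 1.3 * F_mm, by = 0.005)
  k <- wavenumber(gel, lens$frequency_hz)
  max(Mod(.asm_field(lens$annuli_mm, k, numeric(0), 0, z,
                     n_theta = n_theta, n_evanescent = n_evanescent,
                     u_max = u_max)$p))
}

#' Beam metrics of a simulated field
#'
#' Focal length (axial position of the on-axis intensity maximum,
#' quadratically interpolated), focal diameter (lateral full width at
#' half maximum of intensity `|p|^2` in the focal plane) and focal depth
#' (axial intensity FWHM), all interpolated between grid points, plus
#' the peak pressure.  Widths follow the ultrasound convention of -3 dB
#' of intensity (equivalently `|p| = max/sqrt(2)`).
#'
#' @param field an `sfat_field` whose radial grid includes `r = 0`.
#' @return an `sfat_beam_metrics` list: `focal_length_mm`,
#'   `focal_diameter_um`, `focal_depth_um`, `peak_pressure` (same units
#'   as the field).
#' @export
beam_metrics <- function(field) {
  stopifnot(inherits(field, "sfat_field"))
  if (!any(field$r_mm == 0)) {
    stop("field must include the beam axis (r = 0)", call. = FALSE)
  }
  ax <- Mod(field$p[field$r_mm == 0, ])^2
  iz <- which.max(ax)
  if (iz == 1 || iz == length(ax)) {
    stop("on-axis maximum lies on the grid boundary; extend the axial grid",
         call. = FALSE)
  }
  # quadratic (3-point) interpolation of the peak position
  z <- field$z_mm
  dz1 <- z[iz] - z[iz - 1]; dz2 <- z[iz + 1] - z[iz]
  denom <- ax[iz - 1] - 2 * ax[iz] + ax[iz + 1]
  shift <- if (abs(denom) > 0) 0.5 * (ax[iz - 1] - ax[iz + 1]) / denom *
    (dz1 + dz2) / 2 else 0
  focal_z <- z[iz] + shift

  focal_depth <- .fwhm(z, ax, axis = "axial")

  izp <- which.min(abs(z - focal_z))
  lat <- Mod(field$p[, izp])^2
  if (which.max(lat) != 1) {
    stop("lateral profile does not peak on the axis", call. = FALSE)
  }
  half_r <- .half_crossing(field$r_mm, lat, axis = "lateral")
  structure(
    list(focal_length_mm = focal_z,
         focal_diameter_um = 2 * half_r * 1000,
         focal_depth_um = focal_depth * 1000,
         peak_pressure = max(Mod(field$p))),
    class = "sfat_beam_metrics")
}

#' @export
print.sfat_beam_metrics <- function(x, ...) {
  cat(sprintf(
    "beam metrics: focal length %.3f mm, diameter %.1f um, depth %.0f um, peak %.4g\n",
    x$focal_length_mm, x$focal_diameter_um, x$focal_depth_um,
    x$peak_pressure))
  invisible(x)
}

# first half-max crossing beyond the peak (profile must peak at x[1])
.half_crossing <- function(x, y, axis) {
  h <- y[1] / 2
  below <- which(y < h)
  if (!length(below)) {
    stop(sprintf("%s half-maximum not bracketed within the grid", axis),
         call. = FALSE)
  }
  j <- min(below)
  stats::approx(y[c(j - 1, j)], x[c(j - 1, j)], xout = h)$y
}

# FWHM around an interior maximum, linear interpolation of crossings
.fwhm <- function(x, y, axis) {
  i <- which.max(y)
  h <- y[i] / 2
  lo_side <- which(y[1:i] < h)
  hi_side <- which(y[i:length(y)] < h)
  if (!length(lo_side) || !length(hi_side)) {
    stop(sprintf("%s half-maximum not bracketed within the grid", axis),
         call. = FALSE)
  }
  lo <- max(lo_side)
  hi <- i + min(hi_side) - 1
  x_lo <- stats::approx(y[c(lo, lo + 1)], x[c(lo, lo + 1)], xout = h)$y
  x_hi <- stats::approx(y[c(hi - 1, hi)], x[c(hi - 1, hi)], xout = h)$y
  x_hi - x_lo
}

#' Peak in-tumor pressure over a sweep of transducer standoffs
#'
#' For each transducer-to-skin distance, propagates the calibrated field
#' through gel/skin/tumor and records the peak pressure amplitude within
#' the tumor (beyond gel + skin).
#'
#' @param lens an [lens_design()].
#' @param skin_mm skin thickness, mm.
#' @param distances_mm transducer-to-skin distances, mm (default: the six
#'   treatment-plane standoffs 3.1 to 4.6).
#' @param calibration_mpa free-field focal pressure, MPa.
#' @param media named preset list (gel/skin/tumor).
#' @param depth_mm how far into the tumor to search, mm.
#' @param dz_mm axial step, mm.
#' @param n_theta quadrature resolution.
#' @return list with `distances_mm`, `pressure_mpa` (per distance),
#'   `max_mpa`, `min_mpa`.
#' @export
max_tumor_pressure <- function(lens, skin_mm = 0.4,
                               distances_mm = seq(3.1, 4.6, by = 0.3),
                               calibration_mpa = 4.53,
                               media = media_presets(),
                               depth_mm = 2.0, dz_mm = 0.005,
                               n_theta = 6000) {
  stopifnot(length(distances_mm) >= 1)
  k_layers <- vapply(list(media$gel, media$skin, media$tumor), wavenumber,
                     complex(1), frequency_hz = lens$frequency_hz)
  scale <- calibration_mpa / .free_field_peak(lens, media$gel,
                                              n_theta = n_theta)
  focus_reachable <- FALSE
  p_max <- vapply(distances_mm, function(D) {
    z0 <- D + skin_mm
    z <- seq(z0, z0 + depth_mm, by = dz_mm)
    if (z0 < 1.3 * lens$focal_length_mm) focus_reachable <<- TRUE
    amp <- Mod(.asm_field(lens$annuli_mm, k_layers, c(D, skin_mm), 0, z,
                          n_theta = n_theta)$p)
    max(amp) * scale
  }, numeric(1))
  if (!focus_reachable) {
    warning("focus lies outside the tumor for every distance; ",
            "returning boundary values")
  }
  list(distances_mm = distances_mm, pressure_mpa = p_max,
       max_mpa = max(p_max), min_mpa = min(p_max))
}

#' Acoustic power flux through transverse planes
#'
#' Real acoustic power `Int Re(p conj(v_z)) pi r dr` (arbitrary units)
#' carried through planes at the given depths in a homogeneous medium.
#' For a lossless medium the flux is independent of depth, which makes
#' this a sensitive no-spurious-gain check on the propagator; the finite
#' radial window loses only the near-grazing fraction of the spectrum.
#'
#' @param lens lens or annuli matrix.
#' @param med medium (use lossless water for the conservation check).
#' @param frequency_hz operating frequency, Hz.
#' @param z_planes_mm plane depths, mm.
#' @param r_max_mm,dr_mm radial window and step, mm.
#' @param n_theta quadrature resolution.
#' @return numeric vector of fluxes, one per plane.
#' @export
plane_power_flux <- function(lens, med, frequency_hz = NULL,
                             z_planes_mm = c(1, 3, 5),
                             r_max_mm = 20, dr_mm = 0.004,
                             n_theta = 4000) {
  annuli <- .as_annuli(lens)
  if (is.null(frequency_hz)) {
    stopifnot(inherits(lens, "sfat_lens"))
    frequency_hz <- lens$frequency_hz
  }
  k <- wavenumber(med, frequency_hz)
  r <- seq(0, r_max_mm, by = dr_mm)
  out <- .asm_field(annuli, k, numeric(0), r, z_planes_mm,
                    n_theta = n_theta, velocity = TRUE)
  colSums(Re(out$p * Conj(out$v)) * r) * dr_mm * pi
}
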