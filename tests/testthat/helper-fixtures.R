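# Shared fixtures.  Heavy field simulations are memoized so several
# test files can reuse one run.

# Published boundary radii of the reference 5 mm / 20.7 MHz device (um):
# outer edge of the central circle then alternating ring boundaries.
REF_RADII_UM <- c(595, 843, 1035, 1197, 1340, 1471, 1591, 1704, 1811,
                  1912, 2009)

ref_lens <- function() lens_design()

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# simulated water field of the reference lens, grid fine enough for
# interpolated beam metrics
water_field <- function() {
  memo("water_field", {
    lens <- ref_lens()
    propagate_homogeneous(lens, medium_preset("water"),
                          r_mm = seq(0, 0.3, by = 0.002),
                          z_mm = seq(3, 7, by = 0.005))
  })
}

# synthetic separable Gaussian-amplitude beam as an sfat_field
gaussian_field <- function(sigma_r_mm = 0.05, sigma_z_mm = 0.4,
                           z0_mm = 5) {
  r <- seq(0, 0.4, by = 0.001)
  z <- seq(3, 7, by = 0.005)
  p <- outer(exp(-r^2 / (2 * sigma_r_mm^2)),
             exp(-(z - z0_mm)^2 / (2 * sigma_z_mm^2))) + 0i
  structure(list(r_mm = r, z_mm = z, p = p, frequency_hz = 20.7e6,
                 method = "synthetic", media = list(medium_preset("water")),
                 layer_thickness_mm = numeric(0),
                 calibration_scale = NA_real_),
            class = "sfat_field")
}

# hand-built minimal plan for timing edge cases
manual_plan <- function(spots, dwell_s = 0.4, speed_mm_s = 2,
                        n_planes = 1, z_spacing_mm = 0.3) {
  structure(
    list(diameter_mm = NA_real_, spacing_mm = NA_real_,
         convention = "manual", spots = spots,
         n_planes = n_planes, z_spacing_mm = z_spacing_mm,
         z_planes_mm = -(seq_len(n_planes) - 1) * z_spacing_mm,
         z_order = "top-down", dwell_s = dwell_s,
         speed_mm_s = speed_mm_s, spots_per_plane = nrow(spots)),
    class = "sfat_scan_plan")
}
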