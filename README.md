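# sfat

Design and treatment-planning toolkit for **self-focusing acoustic
transducers** (SFATs): planar piezoelectric sources carrying a
microfabricated Fresnel air-cavity lens, used to deliver pulsed
high-frequency (tens of MHz), medium-intensity focused ultrasound to
shallow targets such as subcutaneous tumors.

The package is aimed at people designing or operating such devices who
need the computational side of the workflow without a commercial FEM
seat: lens geometry, the focused field it produces in water and in
layered tissue, the exposure indices a pulse schedule implies, and the
3-axis raster scan that covers a treatment volume.

## What it computes

**Lens design.** Fresnel half-wavelength-band boundary radii from the
path-length condition

    sqrt(r_n^2 + F^2) = F + n * lambda / 2
    =>  r_n = sqrt(n lambda F + (n lambda / 2)^2)

with the transmitting annuli (central disc plus every second ring),
quarter-wave matching-layer thickness `c/(4f)`, and odd-harmonic
thickness-mode resonance `f = n c / (2 t)`.

**Field simulation.** Axisymmetric linear scalar diffraction of the
masked aperture: a Hankel-transform angular-spectrum propagator
(analytic aperture spectrum, per-layer complex wavenumbers
`k = 2 pi f / c + i alpha` for gel/skin/tumor stacks) plus a direct
Rayleigh–Sommerfeld integral and a closed-form piston solution as
independent cross-checks. Beam metrics (focal length, focal
diameter/depth as intensity FWHM) are interpolated, not grid-snapped.
Absolute pressure is set by calibrating the free-field focus to a
measured value.

**Dosimetry.** `I_SPPA = p^2 / (2 rho c)`, `I_SPTA = I_SPPA * duty`,
mechanical index `p_neg / sqrt(f_MHz)`, Sapareto–Dewey CEM43 thermal
dose (R = 0.5 above 43 °C, 0.25 below), FDA-limit safety report, and
substitution insertion-loss / time-of-flight estimators for tissue
acoustic properties.

**Scan planning.** Circular raster spot grids (centered or
half-offset lattice), serpentine routes, treatment timing, voxelised
coverage statistics, and an exact-round-trip G-code (RS-274 subset)
exporter/parser.

## Worked example

```r
library(sfat)

lens <- lens_design()   # 5 mm focus, 20.7 MHz, c = 1465 m/s
lens
#> Fresnel air-cavity lens design
#>   focal length     : 5 mm
#>   frequency        : 20.7 MHz
#>   design c         : 1465 m/s (lambda = 70.77 um)
#>   matching layer   : 26.0 um (quarter wave)
#>   transmitting annuli (inner, outer um):
#>     1st circle     0,   596
#>     2nd ring     844,  1036
#>     ...

field <- propagate_homogeneous(lens, medium_preset("water"),
                               r_mm = seq(0, 0.3, by = 0.002),
                               z_mm = seq(3, 7, by = 0.005))
beam_metrics(field)
#> beam metrics: focal length 4.949 mm, diameter 96.0 um, depth 794 um, peak 12.01

# calibrated peak pressure inside the tumor across the six scan-plane
# standoffs (gel / 0.4 mm skin / tumor)
max_tumor_pressure(lens, skin_mm = 0.4)$pressure_mpa
#> [1] 2.255 2.402 2.559 2.726 2.904 2.951

# exposure indices for the worst-case 3.0 MPa treatment pressure
m <- dose_metrics(3.0, medium_preset("tumor"), pulse_params(60, 1.45e-3))
m
#> dose metrics: p = 3 MPa, I_SPPA = 279.1 W/cm^2, I_SPTA = 24.3 W/cm^2, MI = 0.66
cem43_const(35.6, 11.5) * 60 * 1000   # thermal dose of a full treatment, ms
#> [1] 24.18829

# six-plane raster plan and its G-code
plan <- scan_plan(spots_per_plane = 204)
plan_timing(plan)$total_min
#> [1] 11.25173
gcode <- export_gcode(plan, "scan.gcode")
```

The beam focuses at 4.95 mm (the design is cut for 1465 m/s; water at
1480 m/s stretches the wavelength slightly), with a 96 µm focal
diameter and ~794 µm focal depth. Through 0.4 mm of skin the
2.3–3.0 MPa in-tumor pressures correspond to pulse-average intensities
of 136.8–279.1 W/cm² — an order of magnitude below ablative HIFU — at
a mechanical index of at most 0.66, and the skin-temperature ceiling
of 35.6 °C over an 11.5 min treatment accumulates only ~24 ms of
CEM43 thermal dose.

A thin CLI wrapping the same functions ships in `inst/cli/sfat`
(subcommands `design`, `simulate`, `dose`, `plan`).

## Layout

- `R/` — lens design, field simulation, dosimetry, scan planning,
  waveform/config/IO utilities
- `inst/extdata/media_presets.yaml` — gel, mouse-skin and tumor
  acoustic properties used by the layered simulations
- `vignettes/sfat-methods.Rmd` — models, assumptions, numerical
  choices and limitations
- `tests/testthat/` — unit, property and end-to-end suites
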