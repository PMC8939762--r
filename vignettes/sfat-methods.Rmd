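---
title: "Models and methods behind the sfat toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the sfat toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfat)
```

## The device and the problem

A self-focusing acoustic transducer (SFAT) is a planar piezoelectric
plate with a microfabricated Fresnel air-cavity lens on top.  The lens
consists of annular zones whose boundary radii $r_n$ satisfy the
half-wavelength-band condition

$$\sqrt{r_n^2 + F^2} = F + n\,\lambda/2 ,$$

so that alternate zones arrive at the axial focal point $F$ in phase.
The zones that would interfere destructively are covered by sealed air
cavities, which reflect essentially all incident sound (the air/solid
impedance mismatch is four orders of magnitude); the transmitting
zones are sealed with a quarter-wave matching layer.  The reference
device this package is organised around focuses 20.7 MHz ultrasound
(the 9th thickness-mode harmonic of a 1 mm PZT-4 plate) at 5 mm, and
is used for pulsed medium-intensity treatment of subcutaneous tumors:
low enough intensity to avoid heating and inertial cavitation, focused
tightly enough (around 100 um laterally) to treat selectively.

The toolkit answers the planning questions around such a device: what
do the lens radii have to be; what field does the masked aperture
actually produce; what pressure reaches the tumor through gel, skin
and tumor tissue; what exposure indices and thermal dose does a pulse
schedule imply; and how long does a raster scan of the focus over a
tumor volume take, with what coverage.

## Lens design

`fhwb_boundary_radii()` evaluates the closed form
$r_n = \sqrt{n\lambda F + (n\lambda/2)^2}$ and
`transmit_annuli()` pairs the boundaries into transmitting regions
(central disc, then every second ring).  The one free parameter with
any subtlety is the design sound speed.  The reference device is
specified "in water" without a temperature; a speed of 1465 m/s
(water around 16 C) reproduces its published boundary radii to better
than 3 um across all eleven boundaries, so 1465 m/s is the default
`design_sound_speed_m_s`, and it is configurable.  Radii are kept at
full precision internally and rounded to whole micrometres only when
printed.

## Field simulation

The published characterisation of such devices uses commercial FEM for
the field plots.  The quantities that matter for planning — focal
position, focal widths, attenuated peak pressure — are
diffraction-dominated, so this package uses linear scalar diffraction
instead, with two independent routes:

* **Angular spectrum (default).**  The aperture (uniform normal
  velocity on the transmitting annuli, zero on the blocked rings) has
  an analytic Hankel spectrum, a sum of
  $(b J_1(k_r b) - a J_1(k_r a))/k_r$ terms.  The field at depth $z$
  is the inverse Hankel transform of the spectrum propagated by
  $e^{i k_z z}$ with $k_z = \sqrt{k^2 - k_r^2}$.  The propagating part
  is integrated with the substitution $k_r = k\sin\theta$, which
  removes the $1/k_z$ source-term singularity; the evanescent tail
  ($k_r = k\cosh u$) is integrated explicitly because the $1/k_z$
  spectral weight makes near-cutoff components contribute measurably
  within a few aperture radii of the source.  Defaults: 6000
  propagating and 300 evanescent quadrature nodes, which hold the
  propagator within 0.2% of the closed-form piston solution over
  $z \in [a, 3F]$.
* **Rayleigh–Sommerfeld first integral** (`method = "rayleigh"`), a
  direct two-dimensional quadrature of $e^{ikR}/R$ over the aperture.
  It is slow and intended as a cross-check; the tests require the two
  routes to agree within 1%, and both to agree with the exact on-axis
  piston formula $2|\sin(k(\sqrt{a^2+z^2}-z)/2)|$.

Layered media (gel / skin / tumor) are handled in the angular-spectrum
domain: the lateral wavenumber is conserved across planar interfaces,
and each layer contributes $e^{i k_{z,l} d_l}$ with its own complex
wavenumber $k_l = 2\pi f/c_l + i\alpha_l$.  Interface reflections are
neglected: the impedances of gel, skin and tumor agree within about
8%, a $\le 1\%$ amplitude effect at normal incidence.  Refraction of
the curved tumor surface is likewise ignored (planar layers); the
layered results are attenuation-dominated.

**Calibration.**  Simulated fields are relative until tied to a
measurement.  `propagate_layered()` and `max_tumor_pressure()` scale
the source so that the *all-gel* configuration reproduces a stated
free-field focal pressure (default 4.53 MPa, the hydrophone value at
full drive for the reference device); the same source amplitude then
drives the layered run.  A consequence worth knowing: making the gel
*lossier* raises the inferred drive amplitude, so in-tumor pressure is
monotone decreasing in skin and tumor attenuation but not in gel
attenuation.

**Beam metrics.**  `beam_metrics()` reports the focal position
(quadratically interpolated on-axis intensity maximum) and the focal
diameter and depth as full widths at half maximum of the *intensity*
$|p|^2$ (the -3 dB convention standard in ultrasound
characterisation), with linear interpolation of the half-max
crossings.  Amplitude FWHMs would be about 1.37 times larger for an
Airy-like focus; the intensity convention is the one under which the
simulated widths (96 um lateral, about 794 um axial at 1480 m/s)
match the reference device's published simulated values.

**Energy check.**  With zero attenuation the acoustic power through
any transverse plane is constant.  The integral of $|p|^2$ over a
finite plane is *not* a conserved quantity (near-grazing plane waves
leave any finite window), so `plane_power_flux()` computes the true
flux $\int \mathrm{Re}(p\,\bar v_z)\, \pi r\,\mathrm{d}r$ from the
jointly propagated pressure and axial-velocity spectra; with a 20 mm
window it is constant to better than 2% across $z = 1, 3, 5$ mm, and
the test suite asserts that.

**Grid rules.**  Dense profile grids must resolve the wavelength
(steps coarser than $\lambda/4$ are refused); a handful of isolated
probe points is allowed because the spectral solution is evaluated
pointwise, with no aliasing from the output grid.

## Dosimetry and thermal dose

The chain from pressure to exposure indices uses the plane-wave
intensity relation $I = p^2 / (2\rho c)$, which reproduces the
reference device's published intensity figures from its published
pressures and tissue properties to better than 0.5%:
$I_\mathrm{SPPA}(4.53\,\mathrm{MPa}, \text{water}) = 693\,\mathrm{W/cm^2}$,
$I_\mathrm{SPPA}(3.0\,\mathrm{MPa}, \text{tumor}) = 279.1\,\mathrm{W/cm^2}$.
$I_\mathrm{SPTA}$ is the duty-cycled pulse average (duty cycle
$60\,\mathrm{Hz} \times 1.45\,\mathrm{ms} = 0.087$, kept at full
precision), and the mechanical index is
$p_-(\mathrm{MPa})/\sqrt{f(\mathrm{MHz})}$; under the linear model the
peak negative pressure is taken equal to the simulated amplitude.
`safety_report()` compares against configurable diagnostic limits
(defaults $I_\mathrm{SPPA} < 190\,\mathrm{W/cm^2}$,
$I_\mathrm{SPTA} < 0.72\,\mathrm{W/cm^2}$, $\mathrm{MI} < 1.9$) with a
strict-less convention: a value exactly at a limit fails.

Thermal dose uses the standard Sapareto–Dewey cumulative equivalent
minutes at 43 C with rate constants $R = 0.5$ at or above 43 C and
$0.25$ below; each sampling interval uses its endpoint-mean
temperature, which makes the dose exactly additive over concatenated
records that share their junction sample.  At the 35.6 C maximum skin
temperature of the reference protocol, an 11.5 min treatment is about
24 ms of equivalent time — five orders of magnitude below damaging
doses.

Tissue characterisation follows the substitution method: attenuation
from the log amplitude ratio with and without the sample in a
through-transmission path
($\alpha_s = \alpha_\mathrm{ref} + \ln(A_\mathrm{ref}/A_s)/d$), sound
speed from the arrival-time shift
($1/c_s = 1/c_\mathrm{ref} - \Delta t/d$).  The exact measurement
geometry behind the reference tissue table is not published; these are
the standard substitution forms, and the package labels them as such.
Both estimators exactly invert their forward models, which the tests
exercise by synthesising attenuated and delayed tone bursts and
recovering the parameters (delays via cross-correlation with parabolic
sub-sample refinement).

## Scan planning

`plane_grid()` lays a square lattice over a circle with an inclusive
boundary rule.  Neither natural lattice registration reproduces every
published spot count: at 4.8 mm / 0.3 mm, a centre-anchored lattice
gives 197 spots and a half-offset lattice 208, while the reference
protocol states 204.  Both conventions ship (default `"centered"`),
and `scan_plan(spots_per_plane = ...)` lets a protocol's declared
count drive the dwell budget while the generated route supplies the
travel geometry; with the declared 204 spots the six-plane plan takes
11.25 min against the published 11.5 min (within the 5% a
route-convention difference can explain).  Routes are serpentine
(alternating row direction), plane steps move at the travel speed, and
the default plane order is top-down, matching a focus that starts
0.4 mm below the skin surface and steps deeper.

Coverage statistics rasterise one plane at 10 um voxels: the treated
volume is the union of per-spot cylinders (focal diameter times plane
spacing — at 104 um spots on a 300 um lattice they never overlap, so
the voxelised result is checked against the analytic sum), and the
scanned volume adds the beam swept along the route.  The published
coverage figures for the reference protocol (12.2% treated, 51.0%
including scanned) rest on unstated spot/total-volume conventions, so
this package reports its own conventions alongside the numbers
(default total volume: the scan circle times the covered height,
giving a treated fraction of about 11.5%) rather than asserting the
published ones.

G-code export writes the minimal RS-274 subset a consumer 3-axis
controller understands (G21, G90, G1 at a fixed feedrate, G4 dwells,
Z plane moves) with three-decimal coordinates, and `parse_gcode()`
inverts it exactly at that precision.

## Synthetic fixtures and what the tests do not show

`synth_pulsed_waveform()` generates rectangular-gated tone bursts with
optional Gaussian noise, seeded and reproducible; they emulate
hydrophone records well enough to exercise spectrum, calibration-fit
and delay-estimation code paths.  They do not emulate transducer
ringing, hydrophone bandwidth, nonlinear harmonic content or real
tissue heterogeneity — so passing tests validate the numerics and the
processing chain, not the biology or the transducer electronics.
Likewise the propagation model is linear: nonlinear steepening,
cavitation dynamics and thermal (bioheat) transport are out of scope.

## Problem sizes and numerical defaults

The shipped defaults balance accuracy against desk-scale runtimes:
field grids of about 150 radial x 800 axial points with 6000
propagating quadrature nodes (seconds per field on one core), a 20 mm
/ 5000-point radial window for the flux check, and 10 um voxels for
coverage.  Halving any of them changes the headline metrics by well
under the tolerances quoted above; the tests run the same sizes.
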