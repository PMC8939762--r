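Package: sfat
Title: Design and Treatment-Planning Toolkit for Self-Focusing Acoustic
    Transducers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for high-frequency focused-ultrasound
    tumor treatment with self-focusing acoustic transducers (SFATs).
    Designs Fresnel half-wavelength-band air-cavity lenses, simulates the
    axisymmetric focused pressure field in water and in layered
    gel/skin/tumor tissue by scalar diffraction (Hankel-transform angular
    spectrum or direct Rayleigh-Sommerfeld integral), computes acoustic
    dosimetry (I_SPPA, I_SPTA, mechanical index) and CEM43 thermal dose
    with safety-limit checks, estimates tissue acoustic properties from
    substitution insertion-loss and time-of-flight measurements, and
    generates multi-plane circular raster treatment scans with timing,
    coverage statistics and G-code export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
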