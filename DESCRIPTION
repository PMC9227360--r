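Package: thermoporation
Title: Dosimetry and Temperature-Gradient Electropermeabilization Thresholds
    for Pulsed-Laser Single-Cell Optoporation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physical model chain for femtosecond-laser single-cell
    permeabilization experiments: converts a pulsed-laser exposure
    (wavelength, pulse duration, pulse spacing, average power, spot size)
    into volumetric dose quantities (average power density, per-pulse peak
    energy density, peak areal power density); evaluates the thermoelectric
    temperature-gradient electropermeabilization threshold for a cell
    membrane, including closed-form critical values of pulse spacing, pulse
    duration, energy density and power density; computes Gaussian-beam
    confocal pinhole transmission used for focal registration; and builds
    regime diagrams (critical pulse spacing versus pulse duration at fixed
    energy or power density) with operating-point placement.  A synthetic
    scenario generator produces physically plausible random parameter
    records for property-based testing and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
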