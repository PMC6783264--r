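Package: stimcal
Title: Spectral and Temporal Calibration of Multichromatic Visual Stimulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for calibrating LED-based visual stimulators used in
    vision research with non-human model species. Converts spectrometer
    readings into per-photoreceptor photoisomerisation rates via visual
    pigment nomogram templates, designs opsin-isolating (silent
    substitution) stimuli from cross-activation estimates, builds
    gamma-correction lookup tables from measured intensity series,
    quantifies projected-image spatial resolution from checkerboard
    profiles, simulates LED gating by the scan-retrace blanking signal,
    and computes trial-based response quality and spectral contrast
    statistics for two-photon calcium recordings. Includes synthetic
    generators (band-pass LED spectra, blurred checkerboards, noisy
    sinusoid-driven trial matrices) so the full pipeline can be exercised
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    signal,
    EBImage,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
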