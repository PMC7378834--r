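Package: gliawave
Title: Astrocyte Calcium Imaging Segmentation, Stimulus-Response Fitting and
    Astrocyte-Gamma Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the joint analysis of in vivo two-photon
    astrocyte calcium imaging and electrocorticogram (ECoG) recordings during
    peripheral sensory stimulation. Segments astrocyte territories from a
    structural (SR101-like) channel into soma, arborization and 3x3 micrometre
    microdomain regions using polar-coordinate rules; extracts delta-F/F traces
    and detects calcium events with a 3-standard-deviation criterion; fits
    sigmoid stimulus-response curves to population responses and spectral band
    power; computes FIR-lowpass, Hamming-window spectrogram band power in
    decibels with Welch smoothing and up-state detection; and quantifies
    astrocyte-gamma coupling by Pearson correlation, cross-correlation lag and
    hysteresis loop area. Includes a synthetic-data generator that emulates the
    imaging and electrophysiology, with ground truth for every stage, and a
    phenomenological negative-feedback model of astrocyte gamma dampening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
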