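Package: felreduce
Title: Detector Data Reduction for Serial Crystallography and Single-Particle
    FEL Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline data-reduction toolkit for pixel-detector frames recorded
    at free-electron laser (FEL) sources. Provides dark-run calibration with
    iterative outlier rejection and automatic bad-pixel detection, CrystFEL
    geometry parsing and lab-frame assembly, signal-to-noise based Bragg-peak
    finding and crystal hit classification, q-binned radial averaging and
    single-particle diagnostics (autocorrelations, power spectra, node-distance
    size proxy), fluorescence-spectrum and timing-tool extraction chains, and
    export to multi-event HDF5 and CBF byte-offset files for downstream
    programs such as CrystFEL and nXDS. A small INI-driven pipeline runner
    chains the operations into per-event processing graphs with conditional
    stages and accumulators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ini,
    rhdf5,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
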