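Package: vicarsep
Title: Somatosensory Evoked Potential Analysis with Longest-Run Monte
    Carlo Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of infant somatosensory evoked
    potentials (SEPs). Provides a synthetic generator for epoched
    multi-channel EEG with AR(1) temporal noise and configurable
    condition-by-laterality amplitude effects, a standard ERP
    preprocessing chain (zero-phase elliptic low-pass filtering,
    amplitude-based artifact rejection, baseline correction, average
    referencing, electrode-cluster averaging), and the
    autocorrelation-calibrated Monte Carlo longest-run procedure for
    detecting sustained condition differences in difference waveforms
    while controlling the familywise error rate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
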