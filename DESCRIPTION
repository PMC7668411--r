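Package: megsense
Title: MEG Sensor Selection for Neural Speech Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for identifying a minimal, optimally located subset of
    magnetoencephalography (MEG) gradiometers for decoding imagined and spoken
    phrases. Implements a signal-conditioning chain (Butterworth low-pass,
    line-noise notch, resampling, automated channel and trial rejection, trial
    balancing, window extraction), Daubechies-4 seven-level wavelet band
    decomposition with per-band RMS features, cross-validated polynomial-kernel
    SVM decoding, a step-wise greedy forward sensor-selection algorithm with
    plateau detection and cross-subject consensus analysis, and a stacked
    sparse autoencoder for dimension reduction. A synthetic neuromagnetic
    epoch generator with planted, band-specific class effects provides ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'db4.R'
    'features.R'
    'decode.R'
    'autoencoder.R'
    'select.R'
    'report.R'
    'io.R'
    'megsense-package.R'
    'preprocess.R'
    'synth.R'
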