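Package: ramanlung
Title: Fingerprint Raman Spectroscopy Pipeline for Lung Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis of single-point fingerprint (800-1700 1/cm) Raman
    spectra for discriminating cancer/necrosis from normal/benign lung tissue:
    spectral preprocessing (repeat averaging, dark-count subtraction, instrument
    response correction, wavenumber calibration, BubbleFill baseline removal,
    standard normal variate normalization), quality-factor filtering,
    L1-regularised linear SVM feature selection, leave-one-patient-out
    cross-validated classification, and ROC/permutation evaluation. Includes a
    synthetic cohort generator emulating the acquisition protocol so the whole
    chain is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
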