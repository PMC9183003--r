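Package: fnirsfatigue
Title: Cognitive Fatigue Detection from Two-Channel fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A per-subject pipeline for detecting cognitive fatigue from
    dual-wavelength functional near-infrared spectroscopy (fNIRS) intensity
    recordings. Raw optical intensities are converted to oxygenated,
    deoxygenated and total haemoglobin concentration changes via the
    modified Beer-Lambert law, band-pass filtered, segmented into labelled
    10-second baseline windows, summarised by 26 statistical, temporal,
    spectral and fNIRS-specific features per series, and classified with a
    random forest after recursive feature elimination inside a stratified
    10-fold cross-validation. A synthetic haemodynamic signal generator
    with known ground truth (vasomotor, respiratory and cardiac
    oscillations, drift, sensor noise, class-dependent concentration
    shifts) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    e1071,
    pROC,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
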