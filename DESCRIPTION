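Package: ckcpipe
Title: Corticokinematic Coherence Analysis for EEG and Wrist Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for EEG-based corticokinematic coherence
    (CKC) during periodic passive wrist movement: accelerometer repair and
    double-integration kinematics with movement-regularity statistics,
    EEG cleaning with gel-bridge detection, spherical-spline current
    source density with individually cross-validated regularization,
    Welch coherence spectra with mean- and median-based averaging across
    a method-by-resolution grid, peak/lateralization/SNR metrics, and
    group-level contrasts. Includes a synthetic generator of coupled
    EEG and accelerometer recordings with known ground truth so the whole
    chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
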