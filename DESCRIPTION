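Package: peaprog
Title: Prognosis of Pulseless Electrical Activity from ECG and Thoracic Impedance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automated discrimination of pulseless electrical activity (PEA)
    with favorable evolution to return of spontaneous circulation (faPEA)
    from unfavorable PEA (unPEA), using paired 5-second ECG and thoracic
    impedance (TI) segments. Implements stationary-wavelet ECG denoising,
    extraction of the impedance circulation component by a Kalman smoother
    with a heartbeat-locked Fourier-series observation model
    (Rauch-Tung-Striebel pass), a 17-feature battery (AMSA, band power,
    fuzzy entropy, smoothed nonlinear energy, wavelet-detail dispersion,
    Burg AR noise variance, log power, cross power), random-forest and
    baseline classifiers, patientwise stratified repeated cross-validation,
    recursive importance-based feature selection, and a synthetic segment
    generator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    ranger,
    e1071,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
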