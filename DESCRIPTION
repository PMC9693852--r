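Package: sleepstager
Title: Sleep-Stage Scoring from Single-Channel EEG via Time-Frequency Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic five-stage (W, N1, N2, N3,
    REM) sleep scoring from a single EEG channel. Thirty-second epochs are
    resampled to 256 Hz, band-limited to 0.3-35 Hz with a zero-phase filter,
    converted to time-frequency images by the Fourier synchrosqueezing
    transform (FSST) or an analytic Morse-wavelet continuous wavelet
    transform (CWT), and classified with a convolutional network optionally
    followed by a two-layer bidirectional LSTM. Includes a synthetic
    polysomnography generator with stage-conditional spectral signatures,
    class-imbalance oversampling, stratified splitting and k-fold
    cross-validation, and the full per-class / macro-averaged evaluation
    suite (sensitivity, specificity, precision, F1, accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
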