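Package: ecgradcam
Title: Explainable Residual Convolutional Networks for 12-Lead ECG Interval
    and Amplitude Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures electrocardiographic intervals (PR, QRS, QT), heart
    rate and wave amplitudes (R peak, T peak, J-point elevation) from
    12-lead ECGs with a residual one-dimensional convolutional network, and
    explains the network's predictions with ECGradCAM attention maps
    (gradient-weighted class activation mapping adapted to multichannel
    time series) and wave-blanking occlusion studies. Includes a parametric
    12-lead ECG simulator with exact ground-truth fiducial points so the
    full pipeline is testable without clinical data, a five-fold
    cross-validation harness with Nadam optimisation and time-shift
    augmentation, and the evaluation statistics (MAE, RMSE, ZeroR baseline,
    bias-subtracted MAE, Pearson correlation, accuracy and AUC) used to
    benchmark interval measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
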