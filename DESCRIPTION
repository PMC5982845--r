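Package: thermovitals
Title: Contactless Heart and Respiratory Rate Estimation from Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates heart rate from the sub-pixel vertical
    ballistocardiographic motion of the head and respiratory rate from the
    temperature oscillation around the nostrils in temperature-calibrated
    thermal video. Implements multilevel Otsu segmentation and per-frame
    contrast enhancement, Shi-Tomasi feature selection with pyramidal
    Lucas-Kanade tracking, sliding-window principal component analysis with
    periodicity-based component selection, breath-to-breath interval
    estimation by autocorrelation, average-magnitude-difference and
    maximum-amplitude-pair estimators fused in a Bayesian scheme, agreement
    statistics (RMSE, relative errors, Bland-Altman, CAND), and a synthetic
    thermal-scene generator with known cardiorespiratory ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
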