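Package: ptxsar
Title: Morphometry-Aware SAR Estimation for Parallel-Transmit 7T Head MRI
Version: 0.1.0
Authors@R:
    person("ptxsar", "developers", email = "ptxsar@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for quantifying how subject head morphometry
    affects RF safety estimates in parallel-transmit (pTx) 7 Tesla MRI. Builds
    labeled multi-tissue head phantoms of controllable morphometry, registers
    a reference phantom to a target subject with affine and nonlinear
    (demons-style) registration, generates per-channel complex E and B1+ fields
    for an eight-channel loop array with a quasi-static surrogate, evaluates
    pointwise and 10 g mass-averaged specific absorption rate (SAR) by
    IEC/IEEE 62704-1-style cube growing, forms per-region Q matrices for RF
    shimming, compresses them to virtual observation points (VOPs) with a
    bounded overestimation margin, and reports agreement statistics (Dice
    overlap, B1+ RMSE, Bland-Altman, percent-difference percentiles) between
    morphed and native models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
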