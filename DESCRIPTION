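Package: specwq
Title: Hyperspectral Band Screening and Water-Quality Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for visible-near-infrared hyperspectral estimation of
    wastewater quality parameters (COD, BOD, NH3-N, TDS, TH, TA).
    Implements spectral pretreatment (marginal-band trimming,
    Savitzky-Golay smoothing, standard normal variate), per-band
    relevance screening by Pearson correlation, gray correlation degree,
    variable importance in projection (VIP) from partial least squares
    regression, and a set-pair-analysis fusion of the gray and VIP
    scores; Kennard-Stone calibration/validation partitioning; NIPALS
    partial least squares and extreme learning machine regressors; and
    chemometric model evaluation (R2, RMSE, RPD with categorical
    interpretation, robustness ratio). A synthetic spectra generator
    with known absorption structure supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
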