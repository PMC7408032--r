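Package: serofir
Title: Serum FTIR Fingerprinting with Chemometric QC, Calibration
    Transfer and 1D CNN Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end workflow for machine-learning-assisted stratification
    of serum mid-infrared (FTIR) spectra into healthy, allergic and
    immunotherapy-treated groups: a synthetic serum-spectrum generator with
    class-, subject-, batch- and artifact-level structure; spectral I/O
    (wide-matrix CSV and JCAMP-DX); two-stage quality control (absorbance /
    signal-to-noise / water-vapor checks plus Hotelling T2 versus Q-residual
    outlier charts); the five-step chemometric preprocessing chain
    (truncation, Savitzky-Golay second derivative, multiplicative scatter
    correction, unit-vector normalization, scaling); piecewise direct
    standardization for cross-batch pooling; PCA stratification with
    confidence ellipses and Mardia's multivariate normality screen; and a
    one-dimensional convolutional neural network classifier trained by SGD
    with momentum, L2 penalty and early stopping, tuned by Gaussian-process
    Bayesian optimization, evaluated by repeated stratified hold-out with
    pooled per-class diagnostic metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    lhs,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
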