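Package: pleiomr
Title: Pleiotropy-Robust Mendelian Randomization Estimators and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators for Mendelian randomization with many genetic
    instruments, covering both valid-instrument methods (per-SNP ratio,
    simple/internally/externally weighted polygenic risk scores, two-stage
    least squares, LIML) and pleiotropy-robust methods (weighted MR-Egger
    with intercept test, simple and weighted MR-Median with bootstrap
    standard errors, the L1-penalized sisVIVE estimator with cross-validated
    tuning and the one-standard-error rule, and post-sisVIVE re-estimation).
    One- and two-sample strategies are supported throughout. A synthetic
    cohort generator emulates a weak-instrument BMI-style design with
    trinomial genotypes, shared-confounder errors and three pleiotropy
    scenarios (balanced direct, unbalanced direct, direct plus indirect),
    and a Monte-Carlo evaluation layer reports bias, MSE, coverage, power
    and the false-selection rates of the instrument-selection step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    parallel,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    jsonlite
Config/testthat/edition: 3
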