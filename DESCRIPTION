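Package: ironmr
Title: Two-Sample Mendelian Randomization of Iron Status and Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization with
    GWAS summary statistics, built around the study of systemic iron status
    and stroke risk. Provides reading and validation of summary-statistic
    tables, allele harmonization with palindromic-variant policies,
    concordance-based instrument selection across four iron biomarkers
    (serum iron, log-ferritin, transferrin saturation, transferrin),
    linkage-disequilibrium proxy lookup, per-variant Wald-ratio estimates
    with delta-method standard errors, fixed-effect inverse-variance
    weighted pooling, first-stage F statistics, MR-Egger regression with a
    directional-pleiotropy intercept test, a weighted-median estimator with
    parametric-bootstrap standard errors, and a summary-level simulator of
    two-sample GWAS data with known causal effects and configurable
    pleiotropy for validating every estimator end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
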