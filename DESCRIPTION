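Package: survrank
Title: Ranking Prognostic Factors for Survival After Resection of
    Colorectal Liver Metastases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate prognostic variables for overall survival after
    curative-intent surgery by four complementary engines: the Kaplan-Meier
    product-limit estimator with the two-sample log-rank test, the signed
    definite integral between two Kaplan-Meier curves (a restricted-mean
    survival-time difference used as a ranking statistic), and univariate
    and multivariate Cox proportional-hazards regression fitted by
    Newton-Raphson maximisation of the partial likelihood with Breslow or
    Efron tie handling.  The per-method rankings are aggregated into a
    final ranking.  Includes delimited-text cohort input/output with
    rule-based binarization of continuous markers, a synthetic-cohort
    generator producing proportional-hazards event times with right
    censoring for testing the full pipeline without access to patient
    data, and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
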