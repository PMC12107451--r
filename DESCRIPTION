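Package: gwgcharts
Title: Gestational Weight Gain Reference Charts and Pregnancy Outcome Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cohort- and BMI-specific weight-gain-for-gestational-age
    reference charts from longitudinal antenatal weight measurements using a
    shifted-log mixed-effects model with restricted quadratic splines, derives
    gestational weight gain (GWG) Z-scores and IOM adequacy ratios, and
    estimates BMI-stratified adjusted risk ratios of adverse pregnancy
    outcomes (preterm birth, low birth weight, small-for-gestational-age) by
    GWG Z-score group using modified Poisson regression with robust variance,
    multiple imputation by chained equations and Rubin's-rules pooling.
    Includes a synthetic multi-cohort pregnancy data generator with retained
    ground truth for validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    sandwich,
    mgcv,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
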