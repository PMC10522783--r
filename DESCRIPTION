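Package: saeipv
Title: Small-Area Estimation of Intimate Partner Violence Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: District-level small-area estimation of intimate partner
    violence (IPV) prevalence from a subsampled survey module. Provides
    design-based direct estimation with PSU-level Taylor-linearised
    variances, a logit-scale area-level (Fay-Herriot) random-effects model
    linking direct estimates to census-style auxiliary covariates
    (including a border proximity factor), parametric-bootstrap MSE
    estimation, model and small-area-estimate diagnostics, local Moran's I
    (LISA) hotspot classification with conditional-permutation inference,
    queen-contiguity spatial weights from district polygons, and a
    synthetic-data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lmtest
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
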