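Package: frmeta
Title: Meta-Analysis of Maize Fertilizer Response on Smallholder Farms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesizing on-farm maize fertilizer-trial data
    from Sub-Saharan Africa: harmonization of trial records (units and
    soil-phosphorus test methods), a missing-data cascade (variance
    recovery, correlation-gated linear imputation, predictive mean
    matching), log response-ratio effect sizes with delta-method
    sampling variances, agronomic nitrogen use efficiency, soil
    responsiveness classification, random-effects meta-analysis by
    restricted maximum likelihood with heterogeneity and
    publication-bias diagnostics (funnel data, Egger-type regression
    test, trim-and-fill), weighted subgroup comparison, standardized
    regression with partial-least-squares variable importance (VIP),
    and a seeded synthetic trial-database generator for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, metafor, mixOmics, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
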