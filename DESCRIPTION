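Package: sexmr
Title: Sex-Specific Two-Sample Mendelian Randomization with
    Instrument Heterogeneity Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) on
    sex-specific outcomes using GWAS summary statistics.  Implements
    harmonization and quality control of exposure/outcome summary
    statistics, per-instrument sex-heterogeneity screening (Cochran's Q,
    I-squared, Bonferroni correction) and effect-correlation analysis,
    inverse-variance weighted causal estimation with sensitivity methods
    (weighted median, maximum likelihood, MR-Egger, MR-PRESSO,
    leave-one-out), a formal u test comparing sex-combined against
    sex-specific causal estimates with a leave-one-out jackknife estimate
    of their correlation, a closed-form power calculation for binary
    outcomes, and an individual-level simulation engine quantifying the
    bias incurred when sex-combined instruments are used to estimate a
    sex-specific causal effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor,
    withr
Config/testthat/edition: 3
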