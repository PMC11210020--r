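Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A summary-statistics Mendelian randomization (MR) toolkit built
    around a two-step mediation design: harmonization of GWAS summary
    statistics (allele alignment, palindromic-variant resolution by allele
    frequency, greedy LD clumping, blocklist exclusion), univariable
    estimators (Wald ratio, inverse-variance weighting with multiplicative
    random effects, MR-Egger, weighted median), the MR-PRESSO global,
    outlier, and distortion tests, multivariable MR, mediation decomposition
    by the product of coefficients with delta-method standard errors,
    DerSimonian-Laird random-effects meta-analysis across outcome cohorts,
    instrument-strength and power calculations, and a synthetic
    summary-statistics generator with known causal structure so every stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
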