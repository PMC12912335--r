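Package: mrmediate
Title: Two-Step Drug-Target Mendelian Randomization Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-step drug-target Mendelian randomization (MR)
    mediation analysis from GWAS summary statistics: cis-instrument and
    pQTL instrument construction, allele harmonization, Wald-ratio and
    inverse-variance-weighted estimators with fixed and multiplicative
    random-effects models, weighted-median and weighted-mode robust
    estimators, MR-PRESSO outlier detection, Steiger directionality
    tests, leave-one-out analysis, fixed-effect meta-analysis,
    approximate-Bayes-factor colocalization, proteome-wide FDR
    screening, product-of-coefficients mediation, and a seeded
    synthetic summary-statistics generator so the whole pipeline can be
    exercised and validated without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
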