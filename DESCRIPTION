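Package: mrsummary
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with GWAS
    summary statistics: allele harmonization of exposure, outcome and
    covariate association tables; per-SNP Wald ratios with delta-method
    standard errors; fixed- and random-effects (DerSimonian-Laird)
    inverse-variance-weighted pooling; conversion of per-log-unit odds
    ratios to an ever-vs-never exposure contrast; pleiotropy-robust
    estimators (MR-Egger with parametric-bootstrap standard errors, the
    I2GX weak-instrument statistic, simulation-extrapolation (SIMEX)
    correction for NOME violation, penalized weighted median) and
    multivariable MR; instrument-strength, power and influence
    diagnostics; random-effects meta-analysis of observational study
    estimates with a chi-square comparison against the genetic estimate;
    and a synthetic summary-statistics generator so the whole pipeline is
    testable without external downloads. The worked case study is the
    cannabis-use / schizophrenia analysis with 10 SNP instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
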