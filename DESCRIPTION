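Package: cismr
Title: Cis-Mendelian Randomization with Correlated Genetic Instruments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A two-sample Mendelian randomization pipeline for drug-target
    style analyses that use correlated variants from one or two gene
    regions as instruments. Provides summary-statistics input and allele
    harmonization, gene-region instrument selection with linkage
    disequilibrium (LD) clumping, winner's-curse correction by inverse
    quantile transformation of FDR-adjusted p-values (FIQT), fixed-effect
    meta-analysis of variant-outcome associations across cohorts, a
    generalized least squares inverse-variance-weighted estimator with a
    multiplicative random-effects overdispersion factor, heterogeneity and
    leave-one-out sensitivity analyses, Benjamini-Hochberg multiple-testing
    control, and a seeded generator of synthetic cis-region summary
    statistics for calibration and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
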