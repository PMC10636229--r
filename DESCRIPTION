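Package: gxewas
Title: Genome-Wide Gene-Environment Interaction Analysis for Case-Control Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide gene-environment interaction
    scans in multi-study case-control consortia, motivated by nutritional
    epidemiology of colorectal cancer. Harmonizes dietary folate exposures into
    dietary folate equivalents and analysis covariates; fits per-variant
    logistic models on imputed allele dosages to produce the standard GxE
    interaction test, marginal genetic test, combined-sample and case-only
    gene-environment correlation tests, and joint 2- and 3-degree-of-freedom
    chi-square tests; applies two-step weighted hypothesis testing with
    rank-dependent alpha allocation; pools study-level exposure associations by
    Hartung-Knapp random-effects meta-analysis with heterogeneity and subgroup
    statistics; and estimates genotype-stratified odds ratios with expected
    counts from genotype probabilities. Ships a synthetic consortium generator
    with known genetic architecture so every stage is testable against ground
    truth, plus VCF dosage and TSV phenotype readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
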