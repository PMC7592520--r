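Package: mixprs
Title: Stratified GWAS, Meta-Analysis and Multiethnic Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genetic analysis of cardiometabolic
    traits in two-ancestry cohorts: variant- and sample-level quality control
    with an exact Hardy-Weinberg test and method-of-moments relatedness,
    ancestry-stratified single-variant association on imputed dosages,
    DerSimonian-Laird random-effects meta-analysis, cohort-specific variant
    discovery via dual p-value thresholds and 99% confidence-interval
    separation, Fisher over-representation and eQTL chi-squared enrichment,
    thresholding-pruning polygenic risk scores, multiethnic score mixing with
    cross-validated weights, and top-percentile risk stratification. A seeded
    synthetic-cohort generator (latent-Gaussian linkage blocks, Balding-Nichols
    allele-frequency divergence, liability-threshold diseases) provides fully
    reproducible test beds for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR
Config/testthat/edition: 3
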