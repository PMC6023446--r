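Package: dmetscreen
Title: Statistical, Rule-Mining and Survival Screening of DMET SNP
    Genotype Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A coordinated screening pipeline for pharmacogenomic SNP
    genotype-call tables of the kind produced by drug metabolism enzyme
    and transporter (DMET) microarrays. From one probes-by-samples table
    of diploid genotype calls plus a two-class phenotype assignment and
    optional survival annotations, the package runs three analyses in a
    single execution: per-probe Fisher exact association screening with
    Bonferroni or Benjamini-Hochberg correction and Hardy-Weinberg
    equilibrium testing; Fisher-filtered class-association rule mining
    with an FP-Growth frequent-itemset miner whose rule consequents are
    constrained to the phenotype classes; and per-probe Kaplan-Meier
    screening of overall and progression-free survival ranked by
    log-rank significance, with medians and observed-over-expected
    hazard ratios. A synthetic-data generator plants known association,
    rule and survival effects so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
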