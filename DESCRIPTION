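Package: kmmdr
Title: Gene-Gene Interaction Detection for Survival Phenotypes by
    Multifactor Dimensionality Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects epistatic SNP-SNP interactions associated with a
    censored survival phenotype by multifactor dimensionality reduction
    (MDR). The KM-MDR classifier compares the Kaplan-Meier median survival
    time of each multilocus genotype cell with the overall median to pool
    cells into high- and low-risk groups, and scores candidate SNP
    combinations with squared log-rank statistics under stratified 10-fold
    cross-validation with cross-validation consistency and permutation
    p-values. Comparator classifiers (Surv-MDR per-cell log-rank signs,
    Cox-MDR martingale residuals, AFT-MDR standardized log-normal
    residuals), a purely epistatic penetrance-model simulator with
    calibrated censoring, and a Monte-Carlo harness for type-I error and
    power are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    survival,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
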