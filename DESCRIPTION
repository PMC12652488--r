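Package: gprs
Title: Genetic Distance-Based Clumping and Thresholding for Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs clumping-and-thresholding polygenic risk scores with
    LD clumping windows measured in genetic distance (centimorgans) rather
    than physical distance, preserving long-range linkage-disequilibrium
    regions such as HLA. Includes GWAS summary-statistic quality control and
    allele harmonization, individual-level genotype QC (Hardy-Weinberg exact
    test, kinship pruning, dosage imputation, genetic principal components),
    AUC-driven p-value threshold selection on a stratified train/test split,
    pathway-restricted scores from gene intervals, ordinal score-metabolite
    association by tie-corrected Kendall tau-b, and a synthetic-study
    simulator with an HLA-like low-recombination block for end-to-end
    validation of the genetic-distance window against the traditional
    physical-window comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
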