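Package: HapDepth
Title: Genotype Calling and Imputation from Low-Coverage Sequence Read Depths
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simultaneous genotype calling from low-coverage sequencing
    allele read counts and imputation from SNP-array genotypes in pedigreed
    populations. Per-site allele probabilities are updated by Bayes' rule
    within the two haplotypes selected for each individual from a
    frequency-sorted haplotype library, using binomial read-count
    likelihoods that account for sequencing error. Includes a gene-drop
    pedigree simulator with configurable read depth, read error and array
    subsets, and an accuracy-evaluation harness (percent-correct and
    frequency-centered dosage correlations, overall and by minor allele
    frequency bin).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, GenotypingArray, Software
RoxygenNote: 7.3.3
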