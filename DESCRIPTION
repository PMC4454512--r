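Package: gremlite
Title: SNP Heritability and Genetic Correlation of Human Fertility Traits
    via GREML
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end genomic-relatedness-matrix restricted maximum
    likelihood (GREML) analysis of two female fertility traits, age at
    first birth (AFB) and number of children ever born (NEB): two-cohort
    genotype and phenotype simulation with an additive bivariate genetic
    architecture, SNP quality control (missingness, minor allele
    frequency, exact Hardy-Weinberg test, imputation info score) with
    merge-then-re-QC, genomic relationship matrix construction with
    relatedness pruning and principal components for stratification
    control, univariate and bivariate average-information REML with
    likelihood-ratio tests, and delta-method decomposition of the
    phenotypic correlation into genetic and residual parts. PLINK 1
    bed/bim/fam and GCTA-convention GRM files are read and written.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
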