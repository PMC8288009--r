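Package: introshell
Title: Diagnostic-SNP Introgression, Depth Models and Shell-Outline
    Morphometrics for Mussel Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Mytilus trossulus introgression in
    cultivated blue-mussel stocks and relating it to cultivation depth and
    shell phenotypes. Implements species classification from Me15/16 PCR
    fragments, quality control and filtering of taxon-diagnostic SNP panels,
    per-individual introgression statistics (MT allele frequency, observed
    heterozygosity, hybrid index), depth-stratified contingency and grouped
    logistic / quasibinomial regression models, shell-strength normalization
    and linear model selection, elliptic Fourier outline analysis with shape
    PCA and MANOVA, and a synthetic-cohort generator (genotypes, fragments,
    shell traits, valve outlines, salinity series) that reproduces the
    statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
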