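Package: heritkit
Title: Variance-Component Heritability Estimation from IBS and IBD Relatedness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates narrow-sense and SNP heritability with linear mixed
    models over genetic relationship matrices. Builds identity-by-state (IBS),
    thresholded-IBS, identity-by-descent (IBD) and IBD2 kinship matrices from
    genotypes or pairwise IBD tables; fits variance components by average
    information REML with any number of kinship components; jointly estimates
    total and genotyped-SNP heritability with two relationship matrices; fits
    the ADE model with a likelihood-ratio test for dominance-like effects;
    converts observed-scale estimates of dichotomous traits to the liability
    scale under case-control ascertainment; and provides correlation-based
    heritability estimators for pedigree relationship classes. Includes a
    polygenic phenotype simulator with imposed pairwise IBD structure for
    validating all estimators by parameter recovery. Reads and writes PLINK
    bed/bim/fam files and GCTA binary GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
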