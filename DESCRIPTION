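Package: poolherit
Title: Genomic Heritability from Family-Pool Genotyping-by-Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of genomic heritability at the level of family-pool
    samples genotyped by sequencing. Builds pool-level genomic relationship
    matrices (VanRaden method 1 adapted to F2 family pools) from allele
    frequency matrices, applies depth and frequency quality filters, fits
    multi-component mixed models by average-information REML, and computes
    narrow- and broad-sense heritability estimators with delta-method
    standard errors. Includes a simulator of F2 family-pool GBS data that
    quantifies the downward bias of genomic heritability estimates at low
    sequencing depth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    optparse,
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
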