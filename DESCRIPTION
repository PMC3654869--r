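Package: dipclust
Title: Haplotype-Cluster Diplotype Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association analysis of quantitative or binary traits with
    diplotypes built from haplotype clusters. Detects linkage
    disequilibrium blocks from unphased SNP genotypes (confidence-interval,
    four-gamete and solid-spine rules), estimates block haplotype
    frequencies by expectation-maximization, enumerates all haplotype
    clusters and all diplotype patterns, recodes samples into additive
    0/1/2 doses and tests each pattern by covariate-adjusted linear or
    logistic regression with Bonferroni correction. Includes PLINK PED/MAP
    and phenotype-table readers and a synthetic-cohort generator for fully
    reproducible validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
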