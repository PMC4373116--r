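Package: tagassoc
Title: Weighted Tag SNP-Set Association Tests for Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: SNP-set association testing for case-control genome-wide
    association studies based on weighted tag SNP-sets. Provides a fast
    linkage-disequilibrium graph algorithm that selects tag SNPs from an
    original SNP-set by thresholding pairwise r-squared, a per-SNP weighting
    scheme equal to the square of the single-SNP allelic chi-squared
    statistic, and weighted and unweighted kernel-based association tests
    (KBAT, with permutation p-values) and sequence kernel association tests
    (SKAT, with a scaled chi-squared analytic null or permutation p-values).
    Includes a block-LD haplotype panel simulator with HAPGEN-style genotype
    resampling and a multiplicative disease model, together with replicate
    level type-I-error and power estimation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
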