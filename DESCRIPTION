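Package: clonepanel
Title: Dosage-Based Ploidy Inference and Redundancy Analysis for Clonal
    Germplasm SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for managing clonal, mixed-ploidy germplasm collections
    genotyped with a small biallelic SNP fluorescence (KASP-style) array.
    Models the mapping from polyploid allelic dosage to observable
    fluorescence signal classes, infers accession ploidy from the fraction
    of heterozygous calls that are polyploid-like, detects duplicate
    accessions (redundancy groups) under a one-allele-mismatch rule,
    identifies gene pools by Ward clustering of redundancy-group allele
    frequencies with multiscale-bootstrap approximately unbiased (AU)
    p-values, and builds a permutation-tested kinship network between
    groups. Includes the upstream panel-design step (native VCF filtering,
    flanking-sequence extraction, exact one-dimensional k-means selection
    of representative SNPs) and a synthetic-panel generator emulating a
    mixed-ploidy clonal collection for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
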