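Package: midpass
Title: Genotype Refinement and Benchmarking for Mid-Pass Whole-Genome
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for refining and benchmarking genotype calls from
    mid-pass (1-7x) whole-genome sequencing cohorts. Implements
    call-level genotype-quality (GQ) filtering ahead of within-cohort
    imputation, consistency flagging (IM0-IM3) of imputed against
    sequencing-based calls, and a concordance-evaluation framework
    (recall, precision, non-reference and minor-allele concordance)
    with stratification by minor allele frequency, sequencing
    coverage, genomic region, and variant type. A synthetic cohort
    simulator (mosaic haplotypes, Poisson read depth, likelihood-based
    genotype calls) and a naive nearest-neighbour imputer make every
    stage testable at desk scale, and classification of cohort
    variants against an external reference panel's allele frequencies
    supports novelty and consequence summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
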