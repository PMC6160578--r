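Package: ggkit
Title: Germplasm Genotyping Toolkit for SNP-Based Collection Management
Version: 0.1.0
Authors@R:
    person("WOGB", "Tools", email = "ggkit@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for SNP fingerprinting of clonally propagated
    germplasm collections. Provides marker quality-control filters, pairwise
    multilocus allele-difference matching with gap-based duplicate
    thresholding, redundancy-group detection, per-locus genetic diversity
    statistics (He, Ho, Ne, Shannon I, PIC, fixation and null-allele
    indices, exact Hardy-Weinberg tests), one-way AMOVA with permutation
    phi-st, neighbor-joining trees with locus-resampling bootstrap, and a
    synthetic cohort generator emulating the sample structure of a large
    olive germplasm bank (clonal duplicates, somatic mutants, distinct
    cultivars, differentiated wild material and F1 progeny).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    optparse,
    S4Vectors,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
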