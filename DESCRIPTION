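Package: tnseqr
Title: Quantitative Essentiality Analysis for Transposon Insertion Sequencing
Version: 0.1.0
Authors@R: person("tnseqr", "developers", role = c("aut", "cre"),
    email = "tnseqr@example.org")
Description: Tools for quantitative gene essentiality analysis from
    transposon insertion sequencing (Tn-seq) of serially passaged mutant
    libraries. Provides insertion calling from inverted-repeat tagged reads,
    linear-density and RPKM metrics with genomic repeat masking, unsupervised
    essentiality classification by one-dimensional Gaussian mixture models
    (essential, quasi-essential, quasi-non-essential, non-essential),
    NE-normalized fitness decay trajectories with k-means clustering and
    trapezoidal area-under-curve quantification, annotation-independent
    genome segmentation into essential and non-essential domains by a
    calibrated sliding window, comparison of promoter- and terminator-bearing
    transposon libraries, insertion enrichment statistics over passages (TMM
    normalization, one-tailed tests, COG hypergeometric enrichment), and a
    fully parameterized synthetic library simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
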