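Package: asmflag
Title: Read-Depth Reliability Flagging for Phased Diploid Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates phased diploid genome assemblies from long-read
    alignments. Per-base read depth is run-length encoded, summarised into
    coverage histograms, and modelled with a constrained four-component
    mixture (a Poisson erroneous component plus tied Gaussian components
    for falsely duplicated, haploid and collapsed sequence) fitted by
    expectation-maximization per 5 Mb window. Every base is flagged as
    erroneous, falsely duplicated, reliable haploid, collapsed, or unknown,
    with corrections for human-satellite coverage biases and for
    duplications contradicted by high mapping-quality alignments. Also
    provides alignment hygiene: chimeric/short/divergent alignment
    filtering, removal of reads carrying alternative SNP alleles, and
    marker-based re-ranking of near-tied primary/secondary alignments.
    A seeded simulator generates coverage tracks and alignment fixtures
    with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
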