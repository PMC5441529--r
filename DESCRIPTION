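Package: pleioscan
Title: Cross-Disorder GWAS Pleiotropy Scan and Dual-Disease Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cascaded scan of GWAS summary statistics from two diseases for
    single-nucleotide polymorphisms with opposite-direction (putatively
    pleiotropic) effects, combining p-value thresholding, linkage-disequilibrium
    pruning from a phased haplotype reference panel, cross-trait LD pairing,
    allele harmonization, and gene-region annotation with flanking regions.
    Companion tools build disease protein-interactomes from typed edge lists,
    quantify their overlap with a log-space hypergeometric test, enumerate
    bridging paths, perform pathway enrichment over GMT gene sets with
    Benjamini-Hochberg correction, intersect reciprocal differential-expression
    signatures, and score signatures against perturbagen profiles by rank
    correlation. Seeded synthetic-data generators emulate every external input
    (block-LD haplotype panels, two-trait case/control association statistics
    with planted effects, gene models, paired interactomes with a planted
    shared-interactor set, reciprocal expression tables) with serialized ground
    truth, so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
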