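Package: thetascan
Title: Selection-Signature Scans for Replicated Bidirectionally Selected Lines
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects signatures of selection in replicated, bidirectionally
    selected line pairs from shallow whole-genome sequencing. Implements a
    nested line/replicate/sample/gamete variance decomposition of per-locus
    allele indicators, windowed Weir-Cockerham-style intra-class correlation
    (theta) in sliding SNP windows, genome-wide max-statistic permutation
    thresholds (gamete-level and individual-level), EM-based two-locus
    linkage-disequilibrium estimation with LD-calibrated window size,
    four-gamete-rule haplotype block partitioning, gene-region annotation of
    signatures (promoter, exon, UTR, intron-exon junction, deep intron), and
    a drift-regression estimate of the false discovery rate among fixed or
    lost alleles. Includes a forward-time simulator of a multi-parent
    (MAGIC) base population under replicated within-family truncation
    selection with shallow read-count sequencing, used as the test bed for
    the scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    graphics,
    grDevices,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    IRanges,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
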