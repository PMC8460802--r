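Package: cycleChIP
Title: Joint RNA-seq and ChIP-seq Analysis of Cell-Cycle-Dependent Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes with cell-cycle-dependent expression from a
    synchronized time course by partial least squares (PLS) regression of
    precision-weighted log expression against FACS phase fractions, with
    permutation significance on the variable-importance (VIP) statistic.
    Assigns cyclic genes to cell-cycle phases by correlation with marker
    profiles, quantifies Pol II, H3K4me3 and H3K27me3 ChIP-seq signal in
    binned windows around transcription start sites with input
    normalization, correlates RNA and ChIP profiles through the cycle,
    classifies genes by that correlation and by TSS arrangement, and ranks
    candidate cell-cycle lncRNAs. Includes a synchronized-cell-population
    simulator (wrapped-normal cycle positions with decaying synchrony,
    negative-binomial counts, TSS-localized ChIP reads) that emits every
    pipeline input with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    limma,
    mclust
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, RNASeq, Transcriptomics, Epigenetics, Regression,
    TimeCourse, GeneExpression
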