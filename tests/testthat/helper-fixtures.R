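# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Medium simulation used by several expression/PLS tests.
mediumSim <- function() {
  if (is.null(.fixtures$medium)) {
    .fixtures$medium <- simulateCellCycle(nGenes = 300, seed = 2)
  }
  .fixtures$medium
}

defaultDesign <- function() TimeCourseDesign()

polIIExcludedDesign <- function() {
  TimeCourseDesign(excluded = data.frame(
    assay = "polII", replicate = "Epi2", time = 12))
}

# Brute-force two-sided Fisher p by hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose point
# probability does not exceed the observed one.
enumFisherP <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(ks, c1, n - c1, r1)
  obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Brute-force per-base pileup of 0-based half-open intervals on a toy
# chromosome, and per-bin read counts by fragment-midpoint membership.
brutePileupBins <- function(starts0, strands, chromLen, tss0, geneStrand,
                            readLength = 75, extension = 75,
                            windowSize = 10000, binSize = 50) {
  fragLen <- readLength + extension
  fs <- ifelse(strands == "+", starts0, starts0 + readLength - fragLen)
  mids <- fs + (fragLen - 1) / 2
  w0 <- tss0 - windowSize / 2
  nBins <- windowSize / binSize
  counts <- integer(nBins)
  for (m in mids) {
    if (m >= w0 && m < w0 + windowSize) {
      b <- (m - w0) %/% binSize
      counts[b + 1] <- counts[b + 1] + 1L
    }
  }
  if (geneStrand == "-") counts <- rev(counts)
  counts
}

# 20 kb toy chromosome with a + gene (TSS 7000) and a - gene (TSS 13000),
# 0-based TSS coordinates; the + gene has a long and a short variant.
toyAnnotation <- function() {
  GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = c(7001, 7001, 8501, 12001, 12001),
    end = c(12000, 12000, 10000, 13001, 13001)),
    strand = c("+", "+", "+", "-", "-"),
    type = c("gene", "transcript", "transcript", "gene", "transcript"),
    gene_id = c("gPlus", "gPlus", "gPlus", "gMinus", "gMinus"),
    transcript_id = c(NA, "gPlus.t1", "gPlus.t2", NA, "gMinus.t1"),
    gene_biotype = "protein_coding")
}

# GRanges reads from 0-based starts.
readsFromStarts <- function(starts0, strands, chromLen, chrom = "chrT",
                            readLength = 75) {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts0 + 1, width = readLength),
    strand = strands)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(chromLen, chrom)
  gr
}
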