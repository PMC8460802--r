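#' Select each gene's representative TSS from its longest transcript
#'
#' For every gene the transcript with the largest genomic span is chosen
#' (ties: lowest start coordinate, then lexicographic transcript id) and
#' its 5' end, strand-aware, becomes the representative TSS. All distinct
#' transcript TSSs are recorded along with the multi-TSS span (maximum
#' pairwise distance). Note that for a gene like PCNA, whose expressed
#' short variant starts >5 kb from the long variant's TSS, the long
#' variant's TSS is still the one quantified.
#'
#' @param annotation GRanges of gene/transcript features (1-based, as
#'   imported from GTF) with mcols \code{type}, \code{gene_id},
#'   \code{transcript_id} and optionally \code{gene_biotype}.
#' @return A \linkS4class{TssCatalog}; coordinates are 0-based.
#' @export
selectTss <- function(annotation) {
  tx <- annotation[annotation$type == "transcript"]
  .assert(length(tx) > 0, "annotation contains no transcripts")
  gid <- as.character(tx$gene_id)
  genes <- unique(as.character(
    annotation$gene_id[annotation$type == "gene"]))
  if (length(genes) == 0) genes <- unique(gid)
  missing <- setdiff(genes, gid)
  if (length(missing))
    stop("gene(s) without transcripts: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  st <- GenomicRanges::start(tx); en <- GenomicRanges::end(tx)
  strnd <- as.character(GenomicRanges::strand(tx))
  tss0 <- ifelse(strnd == "+", st - 1, en - 1)
  chrom <- as.character(GenomeInfoDb::seqnames(tx))
  bio <- if ("gene_biotype" %in% colnames(S4Vectors::mcols(tx)))
    as.character(tx$gene_biotype) else NA_character_
  ord <- order(gid, -(en - st), st, as.character(tx$transcript_id))
  first <- !duplicated(gid[ord])
  rep <- ord[first]
  repTab <- data.frame(gene_id = gid[rep], chrom = chrom[rep],
                       tss = tss0[rep], strand = strnd[rep],
                       transcript_id = as.character(tx$transcript_id)[rep],
                       biotype = bio[rep], stringsAsFactors = FALSE)
  spanTab <- do.call(rbind, lapply(split(tss0, gid), function(p) {
    u <- unique(p)
    data.frame(nTss = length(u), span = max(u) - min(u))
  }))
  repTab$nTss <- spanTab[repTab$gene_id, "nTss"]
  repTab$span <- spanTab[repTab$gene_id, "span"]
  allKeep <- !duplicated(paste(gid, tss0))
  allTss <- S4Vectors::DataFrame(gene_id = gid[allKeep],
                                 chrom = chrom[allKeep],
                                 tss = tss0[allKeep],
                                 strand = strnd[allKeep])
  new("TssCatalog", genes = S4Vectors::DataFrame(repTab), allTss = allTss)
}

#' Extended-read coverage and RPKM scaling
#'
#' Each read is extended from its 5' end in its strand direction to
#' \code{readLength + extension} bases (75 + 75 = 150, the fragment size)
#' and clipped at chromosome ends; coverage is the pileup of extended
#' reads. The RPKM of any interval is
#' \code{count * 1e9 / (length * totalReads)}. Extended-fragment midpoints
#' (pre-clipping) are kept for unique read-to-bin assignment.
#'
#' @param reads GRanges of aligned reads (1-based; e.g. from
#'   \code{\link{readBedReads}}).
#' @param chromSizes named chromosome lengths.
#' @param extension bases added past the read 3' end (default 75).
#' @param readLength read length (default 75).
#' @return list with \code{coverage} (RleList), \code{totalReads},
#'   \code{midpoints} (data.frame chrom, pos 0-based), \code{clipped}
#'   (count of reads clipped at chromosome ends) and the parameters.
#' @export
computeCoverage <- function(reads, chromSizes, extension = 75,
                            readLength = 75) {
  fragLen <- readLength + extension
  ext <- suppressWarnings(
    GenomicRanges::resize(reads, width = fragLen, fix = "start"))
  # fragment centers kept as half-integers so that bin assignment is
  # exactly mirror-symmetric (no center ever falls on a bin boundary)
  mid <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(ext)),
    pos = GenomicRanges::start(ext) - 1 + (fragLen - 1) / 2)
  GenomeInfoDb::seqlevels(ext) <- names(chromSizes)
  GenomeInfoDb::seqlengths(ext) <- unname(chromSizes)
  trimmed <- suppressWarnings(GenomicRanges::trim(ext))
  nClipped <- sum(GenomicRanges::width(trimmed) < fragLen |
                  GenomicRanges::start(ext) < 1)
  if (nClipped > 0)
    warning(nClipped, " read(s) extended beyond chromosome bounds; clipped")
  list(coverage = GenomicRanges::coverage(trimmed),
       totalReads = length(reads), midpoints = mid, clipped = nClipped,
       extension = extension, readLength = readLength,
       chromSizes = chromSizes)
}

#' RPKM of an interval
#'
#' @param count reads in the interval.
#' @param length interval length in bp.
#' @param totalReads library size.
#' @return reads per kilobase per million mapped reads.
#' @examples
#' intervalRpkm(2, 50, 1e6)  # 40
#' @export
intervalRpkm <- function(count, length, totalReads)
  count * 1e9 / (length * totalReads)

#' Bin the 10 kb TSS window into 200 bins of 50 bp
#'
#' The window is [TSS - 5000, TSS + 5000) in 0-based genome coordinates,
#' split into 200 bins of 50 bp. Each read belongs to exactly one bin: the
#' bin containing its extended-fragment midpoint. For minus-strand genes
#' the bin order is reversed so the bin index increases downstream of the
#' TSS; the point TSS + 75 (strand-aware) then falls in oriented bin 101
#' (0-based) for either strand. Bins extending past chromosome ends are
#' flagged partial.
#'
#' @param cov object from \code{\link{computeCoverage}}.
#' @param catalog a \linkS4class{TssCatalog}.
#' @param windowSize,binSize window and bin sizes in bp (defaults 10000,
#'   50).
#' @return list with \code{counts} and \code{rpkm} (genes x 200, oriented),
#'   \code{partial} (logical genes x 200) and \code{totalReads}.
#' @export
binTssRegion <- function(cov, catalog, windowSize = 10000, binSize = 50) {
  nBins <- windowSize / binSize
  tab <- tssTable(catalog)
  counts <- matrix(0L, nrow(tab), nBins,
                   dimnames = list(tab$gene_id, NULL))
  partial <- matrix(FALSE, nrow(tab), nBins,
                    dimnames = list(tab$gene_id, NULL))
  byChrom <- split(cov$midpoints$pos, cov$midpoints$chrom)
  byChrom <- lapply(byChrom, sort)
  for (i in seq_len(nrow(tab))) {
    w0 <- tab$tss[i] - windowSize / 2
    pos <- byChrom[[tab$chrom[i]]]
    if (!is.null(pos) && length(pos)) {
      lo <- findInterval(w0 - 0.25, pos) + 1
      hi <- findInterval(w0 + windowSize - 0.25, pos)
      if (hi >= lo) {
        idx <- (pos[lo:hi] - w0) %/% binSize
        counts[i, ] <- tabulate(idx + 1, nbins = nBins)
      }
    }
    chromLen <- cov$chromSizes[[tab$chrom[i]]]
    binStart <- w0 + binSize * (seq_len(nBins) - 1)
    partial[i, ] <- binStart < 0 | (binStart + binSize) > chromLen
    if (tab$strand[i] == "-") {
      counts[i, ] <- rev(counts[i, ])
      partial[i, ] <- rev(partial[i, ])
    }
  }
  list(counts = counts,
       rpkm = intervalRpkm(counts, binSize, cov$totalReads),
       partial = partial, totalReads = cov$totalReads)
}

#' Normalize binned ChIP signal to input
#'
#' Each ChIP bin RPKM is divided by the mean input RPKM of the same
#' window (averaged over the window's bins and over input samples) on a
#' log2 scale with a pseudocount:
#' \code{log2((chip + pc) / (meanInput + pc))}. A gene whose promoter
#' lacks enrichment over input therefore gets negative values. The
#' alternative genome-wide input mean is exposed via \code{inputMean}.
#'
#' @param chipBins result of \code{\link{binTssRegion}} for a ChIP sample.
#' @param inputBins list of \code{\link{binTssRegion}} results, one per
#'   input sample (at least one required).
#' @param pseudocount stabilizing offset (default 0.5).
#' @param inputMean \code{"window"} (default) for the window-local input
#'   mean per gene, \code{"genome"} for one global mean over all windows.
#' @return matrix genes x 200 of log2 input-normalized values.
#' @export
normalizeToInput <- function(chipBins, inputBins, pseudocount = 0.5,
                             inputMean = c("window", "genome")) {
  inputMean <- match.arg(inputMean)
  .assert(length(inputBins) >= 1, "missing input track")
  inpAvg <- Reduce(`+`, lapply(inputBins, `[[`, "rpkm")) / length(inputBins)
  denom <- if (inputMean == "window") rowMeans(inpAvg) else mean(inpAvg)
  log2((chipBins$rpkm + pseudocount) /
       (denom + pseudocount))
}

# Oriented 0-based bin index of the point TSS + 75 in a 10 kb/50 bp window.
.tssPointBin <- function(windowSize = 10000, binSize = 50, offset = 75)
  (windowSize / 2 + offset) %/% binSize

#' Scalar TSS-point signal per gene
#'
#' The scalar signal of a gene is the normalized value of the oriented bin
#' containing the point TSS + 75 (bin 101, 0-based). The signal is missing
#' where that bin is flagged partial.
#'
#' @param normBins matrix from \code{\link{normalizeToInput}}.
#' @param binInfo the \code{\link{binTssRegion}} result carrying partial
#'   flags (optional).
#' @return named numeric, one value per gene.
#' @export
tssSignal <- function(normBins, binInfo = NULL) {
  j <- .tssPointBin() + 1
  out <- normBins[, j]
  if (!is.null(binInfo)) out[binInfo$partial[, j]] <- NA_real_
  out
}

#' Quantify TSS signals for a set of samples
#'
#' Full quantification path for one antibody: extended-read coverage,
#' 200-bin TSS windows, input normalization (input bins averaged over all
#' input samples), and the scalar TSS-point signal.
#'
#' @param chipReads named list of read GRanges, one per sample.
#' @param inputReads named list of input read GRanges.
#' @param catalog a \linkS4class{TssCatalog}.
#' @param chromSizes named chromosome lengths.
#' @param ... passed to \code{\link{normalizeToInput}}.
#' @return list with \code{signal} (genes x samples matrix of scalar
#'   TSS signals) and \code{bins} (list of normalized bin matrices).
#' @export
quantifyTssSignals <- function(chipReads, inputReads, catalog, chromSizes,
                               ...) {
  .assert(length(inputReads) >= 1, "missing input track")
  inputBins <- lapply(inputReads, function(r)
    binTssRegion(computeCoverage(r, chromSizes), catalog))
  norm <- lapply(chipReads, function(r) {
    b <- binTssRegion(computeCoverage(r, chromSizes), catalog)
    list(values = normalizeToInput(b, inputBins, ...), info = b)
  })
  signal <- vapply(norm, function(x) tssSignal(x$values, x$info),
                   numeric(nrow(tssTable(catalog))))
  rownames(signal) <- tssTable(catalog)$gene_id
  list(signal = signal, bins = lapply(norm, `[[`, "values"))
}

#' Call promoter mark presence and combinations
#'
#' A mark is present at a gene's promoter if its normalized TSS signal is
#' positive in at least \code{minPositive} time points (per-time-point
#' means, honoring each antibody's exclusions). Combinations are logical
#' ANDs: Pol II/K4, Pol II/K27 and the bivalent K4/K27 promoter state.
#'
#' @param signals named list of genes x samples scalar-signal matrices,
#'   with names among polII, H3K4me3, H3K27me3.
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param geneSet genes over which percentages are computed (default: all
#'   genes present in every matrix).
#' @param minPositive minimum positive time points (default 2, boundary
#'   inclusive).
#' @return list with \code{presence} (logical data.frame per mark and
#'   combination), \code{percent} (percentages over assessable genes) and
#'   \code{nExcluded} (genes with all signals missing).
#' @export
callPromoterMarks <- function(signals, design, geneSet = NULL,
                              minPositive = 2) {
  genes <- Reduce(intersect, lapply(signals, rownames))
  if (!is.null(geneSet)) genes <- intersect(genes, geneSet)
  pres <- lapply(signals, function(m) {
    prof <- meanProfile(m[genes, , drop = FALSE], design)
    allNA <- rowSums(!is.na(prof)) == 0
    p <- rowSums(prof > 0, na.rm = TRUE) >= minPositive
    p[allNA] <- NA
    p
  })
  df <- data.frame(gene = genes, row.names = NULL)
  for (ab in names(pres)) df[[ab]] <- unname(pres[[ab]])
  if (all(c("polII", "H3K4me3") %in% names(pres)))
    df$polII_K4 <- df$polII & df$H3K4me3
  if (all(c("polII", "H3K27me3") %in% names(pres)))
    df$polII_K27 <- df$polII & df$H3K27me3
  if (all(c("H3K4me3", "H3K27me3") %in% names(pres)))
    df$bivalent <- df$H3K4me3 & df$H3K27me3
  assessable <- rowSums(!is.na(df[, -1, drop = FALSE])) > 0
  pct <- vapply(df[assessable, -1, drop = FALSE],
                function(x) 100 * mean(x, na.rm = TRUE), numeric(1))
  list(presence = df, percent = pct, nExcluded = sum(!assessable))
}
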