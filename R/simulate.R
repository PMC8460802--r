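#' Ground-truth gene parameters for a simulated cell population
#'
#' Draws a per-gene parameter table for the simulator: biotype, a cyclic
#' flag with peak phase and log2 amplitude, a baseline log2 expression
#' drawn from a bimodal (high/low) mixture, negative-binomial dispersion,
#' per-antibody ChIP coupling flags with a coupling slope, and a TSS layout
#' (single TSS; multiple TSSs within 1 kb; or a widely separated TSS pair).
#' A designated subset of cyclic genes serve as phase markers: their peak
#' phases are pinned to the mid-arc of each of the five phase labels.
#'
#' @param nGenes number of genes (default 1000).
#' @param cyclicFrac fraction of cyclic genes (default 0.1).
#' @param lncFrac fraction of lncRNA biotype genes (default 0.05).
#' @param amplitudeRange log2 amplitude range for cyclic genes
#'   (default \code{c(1, 2)}).
#' @param dispersion negative-binomial overdispersion (default 0.05).
#' @param coupledFrac fraction of cyclic genes whose Pol II/H3K4me3 (and,
#'   negatively, H3K27me3) signal is coupled to expression (default 0.5).
#' @param markersPerPhase cyclic genes pinned to each phase label as
#'   markers (default 4).
#' @param seed integer master seed.
#' @return A \code{DataFrame} with one row per gene; columns gene_id,
#'   biotype, cyclic, peak_phase, amplitude, baseline, dispersion,
#'   coupled, slope, marker, marker_phase, n_tss, tss_spacing,
#'   neighbor_dist.
#' @export
makeSyntheticTruth <- function(nGenes = 1000, cyclicFrac = 0.1,
                               lncFrac = 0.05,
                               amplitudeRange = c(1, 2),
                               dispersion = 0.05, coupledFrac = 0.5,
                               markersPerPhase = 4, seed = 1) {
  .withSeed(.subSeed(seed, "truth"), {
    gene_id <- sprintf("G%05d", seq_len(nGenes))
    nCyc <- round(nGenes * cyclicFrac)
    cyclic <- c(rep(TRUE, nCyc), rep(FALSE, nGenes - nCyc))
    biotype <- rep("protein_coding", nGenes)
    nLnc <- round(nGenes * lncFrac)
    # spread lncRNAs over cyclic and non-cyclic genes
    lncIdx <- unique(round(seq(1, nGenes, length.out = max(nLnc, 1))))[
      seq_len(nLnc)]
    biotype[lncIdx] <- "lncRNA"
    peak_phase <- runif(nGenes)
    amplitude <- ifelse(cyclic,
                        runif(nGenes, amplitudeRange[1], amplitudeRange[2]),
                        0)
    # bimodal baseline: highly vs lowly expressed modes; cyclic genes are
    # drawn from the high mode so the reference-set floor retains both
    highMode <- cyclic | (runif(nGenes) < 0.6)
    baseline <- ifelse(highMode, rnorm(nGenes, 8, 0.8), rnorm(nGenes, 3, 0.8))
    coupled <- cyclic & (seq_len(nGenes) <= round(nCyc * coupledFrac))
    marker <- rep(FALSE, nGenes)
    marker_phase <- rep(NA_character_, nGenes)
    labs <- phaseLevels()
    mid <- c("G1/S" = 0.01, "S" = 0.21, "G2" = 0.425,
             "G2/M" = 0.55, "M/G1" = 0.775)
    mi <- 0L
    for (lab in labs) {
      idx <- which(cyclic)[mi + seq_len(markersPerPhase)]
      idx <- idx[!is.na(idx)]
      marker[idx] <- TRUE
      marker_phase[idx] <- lab
      peak_phase[idx] <- mid[[lab]] + runif(length(idx), -0.02, 0.02)
      mi <- mi + markersPerPhase
    }
    layout <- sample(c("single", "multi1kb", "pair"), nGenes,
                     replace = TRUE, prob = c(0.4, 0.5, 0.1))
    n_tss <- ifelse(layout == "single", 1L,
                    ifelse(layout == "pair", 2L,
                           sample(2:3, nGenes, replace = TRUE)))
    tss_spacing <- ifelse(layout == "single", 0,
                          ifelse(layout == "pair",
                                 round(runif(nGenes, 5500, 8000)),
                                 round(runif(nGenes, 100, 450))))
    neighbor_dist <- ifelse(runif(nGenes) < 0.5,
                            round(runif(nGenes, 3000, 8000)),
                            25000)
    S4Vectors::DataFrame(
      gene_id = gene_id, biotype = biotype, cyclic = cyclic,
      peak_phase = peak_phase %% 1, amplitude = amplitude,
      baseline = baseline, dispersion = dispersion,
      coupled = coupled, slope = 1, marker = marker,
      marker_phase = marker_phase, n_tss = n_tss,
      tss_spacing = tss_spacing, neighbor_dist = neighbor_dist)
  })
}

#' Simulate a count matrix from latent cyclic expression
#'
#' A single cell at cycle position theta expresses gene g at
#' \code{baseline + amplitude * cos(2*pi*(theta - peak_phase))} (log2).
#' The population latent at each time point is the expectation of this
#' cosine bump under the time point's wrapped-normal position
#' distribution, computed by numerical integration on a fixed grid; loss
#' of synchrony therefore damps the oscillation cycle over cycle. Counts
#' are drawn negative-binomial with mean equal to the library-size-scaled
#' linear latent (latent treated as log2 CPM) and the gene's dispersion.
#'
#' @param truth DataFrame from \code{\link{makeSyntheticTruth}}.
#' @param facs a \linkS4class{FacsFractions} (provides the per-time-point
#'   position distributions).
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param librarySizes optional named per-sample library sizes (positive);
#'   default log-normal around 1e6, drawn from the seeded stream.
#' @param seed integer master seed.
#' @param gridSize integration grid size (default 512).
#' @return list with \code{counts} (integer matrix genes x samples),
#'   \code{latents} (noise-free log2 CPM latents, genes x samples) and
#'   \code{librarySizes}.
#' @export
simulateExpression <- function(truth, facs, design, librarySizes = NULL,
                               seed = 1, gridSize = 512) {
  grid <- sampleGrid(design)
  if (is.null(librarySizes)) {
    librarySizes <- .withSeed(.subSeed(seed, "libsizes"),
                              rlnorm(nrow(grid), log(1e6), 0.1))
    names(librarySizes) <- grid$sample
  }
  .assert(all(librarySizes > 0), "library sizes must be positive")
  .assert(all(grid$sample %in% names(librarySizes)),
          "librarySizes must name every design sample")
  pos <- positionParams(facs)
  theta <- (seq_len(gridSize) - 0.5) / gridSize
  # first trigonometric moments of the position distribution per time point
  trig <- t(vapply(seq_len(nrow(pos)), function(i) {
    w <- .wnDensity(theta, pos$mean[i], pos$sd[i])
    w <- w / sum(w)
    c(ct = sum(w * cos(2 * pi * theta)), st = sum(w * sin(2 * pi * theta)))
  }, numeric(2)))
  cosPsi <- cos(2 * pi * truth$peak_phase)
  sinPsi <- sin(2 * pi * truth$peak_phase)
  latentT <- vapply(seq_len(nrow(pos)), function(i) {
    truth$baseline + truth$amplitude *
      (trig[i, "ct"] * cosPsi + trig[i, "st"] * sinPsi)
  }, numeric(nrow(truth)))  # genes x time points
  ti <- match(grid$time, design@timePoints)
  latents <- latentT[, ti, drop = FALSE]
  dimnames(latents) <- list(truth$gene_id, grid$sample)
  counts <- .withSeed(.subSeed(seed, "counts"), {
    m <- matrix(0L, nrow(latents), ncol(latents), dimnames = dimnames(latents))
    for (s in seq_len(ncol(latents))) {
      mu <- 2^latents[, s] * librarySizes[[grid$sample[s]]] / 1e6
      m[, s] <- rnbinom(nrow(latents), mu = mu, size = 1 / truth$dispersion)
    }
    m
  })
  list(counts = counts, latents = latents, librarySizes = librarySizes)
}

#' Generate a gene/transcript annotation realizing the truth TSS layouts
#'
#' Genes are laid out along one chromosome so that each gene's transcripts
#' realize its TSS layout (single TSS, multiple TSSs within 1 kb, or a
#' widely separated pair) and neighboring genes' nearest TSSs sit at the
#' requested distances. Genes requesting the same neighbor distance are
#' placed adjacently, so a distance is realized exactly whenever at least
#' two genes request it; distance groups are separated by a 30 kb buffer.
#' Transcripts of a gene share a 3' end, so the most distal TSS always
#' belongs to the longest transcript.
#'
#' @param truth DataFrame from \code{\link{makeSyntheticTruth}}.
#' @param genomeLength optional chromosome length; if the layout does not
#'   fit an error is raised. Default: sized to fit.
#' @param seed integer master seed (strands).
#' @param chrom chromosome name (default "chr1").
#' @param transcriptLength body length added past the most proximal TSS
#'   (default 2000).
#' @return list with \code{annotation} (GRanges of gene and transcript
#'   features, 1-based) and \code{chromSizes} (named numeric).
#' @export
generateAnnotation <- function(truth, genomeLength = NULL, seed = 1,
                               chrom = "chr1", transcriptLength = 2000) {
  n <- nrow(truth)
  strand <- .withSeed(.subSeed(seed, "annotation"),
                      sample(c("+", "-"), n, replace = TRUE))
  ord <- order(truth$neighbor_dist, seq_len(n))
  margin <- transcriptLength + 10000
  cursor <- margin
  rows <- vector("list", n)
  lastDist <- NA
  for (k in seq_len(n)) {
    i <- ord[k]
    d <- truth$neighbor_dist[i]
    if (k > 1) cursor <- cursor + (if (identical(d, lastDist)) d else 30000)
    lastDist <- d
    offs <- if (truth$n_tss[i] == 1) 0 else
      round(seq(0, truth$tss_spacing[i], length.out = truth$n_tss[i]))
    tss <- cursor + offs  # 0-based TSS positions
    if (strand[i] == "+") {
      tes <- max(tss) + transcriptLength
      txStart <- tss; txEnd <- rep(tes, length(tss))
    } else {
      tes <- min(tss) - transcriptLength
      txStart <- rep(tes, length(tss)); txEnd <- tss + 1
    }
    rows[[i]] <- data.frame(
      gene_id = truth$gene_id[i],
      transcript_id = sprintf("%s.t%d", truth$gene_id[i], seq_along(tss)),
      start0 = txStart, end0 = txEnd, strand = strand[i],
      biotype = truth$biotype[i])
    cursor <- cursor + max(offs)
  }
  tx <- do.call(rbind, rows)
  need <- max(tx$end0) + margin
  if (is.null(genomeLength)) genomeLength <- need
  if (genomeLength < need)
    stop("TSS layouts do not fit in genome_length ", genomeLength,
         " (need ", need, ")", call. = FALSE)
  txGr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = tx$start0 + 1, end = tx$end0),
    strand = tx$strand, type = "transcript", gene_id = tx$gene_id,
    transcript_id = tx$transcript_id, gene_biotype = tx$biotype)
  geneRows <- split(seq_len(nrow(tx)), tx$gene_id)
  gIds <- names(geneRows)
  gStart <- vapply(geneRows, function(ii) min(tx$start0[ii]), numeric(1))
  gEnd <- vapply(geneRows, function(ii) max(tx$end0[ii]), numeric(1))
  gStrand <- vapply(geneRows, function(ii) tx$strand[ii[1]], "")
  gBio <- vapply(geneRows, function(ii) tx$biotype[ii[1]], "")
  geneGr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = gStart + 1, end = gEnd),
    strand = gStrand, type = "gene", gene_id = gIds,
    transcript_id = NA_character_, gene_biotype = gBio)
  ann <- sort(c(geneGr, txGr))
  chromSizes <- stats::setNames(genomeLength, chrom)
  GenomeInfoDb::seqlengths(ann) <- chromSizes
  list(annotation = ann, chromSizes = chromSizes)
}

#' Simulate TSS-localized ChIP and uniform input reads
#'
#' For each antibody and sample, each gene receives a Poisson number of
#' reads around its representative TSS. For coupled genes the Poisson
#' intensity is \code{base * 2^(slope * (latent - baseline))}, so Pol II
#' and H3K4me3 (positive slope) track expression while H3K27me3 (negative
#' slope, and a higher base at lowly expressed genes) tracks silencing;
#' uncoupled genes get time-constant intensity. Fragment centers are drawn
#' from a triangular kernel of configurable half-width centred on the TSS;
#' each 75 bp read sits at one end of a 150 bp fragment on a random
#' strand, so downstream 75 bp extension reconstructs the fragment. Input
#' samples get uniform genome background.
#'
#' @param truth DataFrame from \code{\link{makeSyntheticTruth}}.
#' @param latents genes x samples latent log2 CPM from
#'   \code{\link{simulateExpression}}.
#' @param catalog a \linkS4class{TssCatalog} (see \code{\link{selectTss}}).
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param chromSizes named chromosome lengths.
#' @param antibodies subset of c("polII", "H3K4me3", "H3K27me3").
#' @param genes optional gene ids to simulate reads for (default: all in
#'   the catalog).
#' @param meanReadsPerGene expected reads per gene per sample (default 200).
#' @param inputDepth expected input reads per sample (default: number of
#'   genes x meanReadsPerGene).
#' @param fragmentLength sonicated fragment size (default 150).
#' @param readLength sequenced read length (default 75).
#' @param kernelHalfWidth triangular kernel half-width in bp (default 500).
#' @param seed integer master seed.
#' @return nested list \code{reads[[antibody]][[sample]]} of sorted
#'   GRanges (1-based, stranded); antibodies plus an \code{"input"} entry.
#' @export
simulateChipReads <- function(truth, latents, catalog, design, chromSizes,
                              antibodies = c("polII", "H3K4me3", "H3K27me3"),
                              genes = NULL, meanReadsPerGene = 200,
                              inputDepth = NULL, fragmentLength = 150,
                              readLength = 75, kernelHalfWidth = 500,
                              seed = 1) {
  .assert(meanReadsPerGene > 0, "depth must be positive")
  tab <- tssTable(catalog)
  if (!is.null(genes)) tab <- tab[tab$gene_id %in% genes, , drop = FALSE]
  .assert(nrow(tab) > 0, "no genes to simulate reads for")
  truth <- truth[match(tab$gene_id, truth$gene_id), , drop = FALSE]
  grid <- sampleGrid(design)
  if (is.null(inputDepth)) inputDepth <- nrow(tab) * meanReadsPerGene
  .assert(inputDepth > 0, "depth must be positive")
  slopes <- c(polII = 1, H3K4me3 = 1, H3K27me3 = -0.5)
  half <- fragmentLength / 2
  genomeLen <- chromSizes[[1]]
  chromName <- names(chromSizes)[1]
  latc <- latents[tab$gene_id, grid$sample, drop = FALSE] - truth$baseline
  out <- list()
  .withSeed(.subSeed(seed, "reads"), {
    for (ab in antibodies) {
      sl <- slopes[[ab]] * truth$slope
      base <- rep(meanReadsPerGene, nrow(tab))
      if (ab == "H3K27me3") {
        # repressive background: stronger at lowly expressed genes
        base <- meanReadsPerGene *
          ifelse(truth$baseline < stats::median(truth$baseline), 1, 0.3)
      }
      out[[ab]] <- lapply(seq_len(nrow(grid)), function(s) {
        lambda <- ifelse(truth$coupled, base * 2^(sl * latc[, s]), base)
        nr <- rpois(length(lambda), lambda)
        ctr <- rep(tab$tss, nr) +
          round((runif(sum(nr)) - runif(sum(nr))) * kernelHalfWidth)
        ctr <- ctr[ctr >= half & ctr <= genomeLen - half]
        sgn <- sample(c("+", "-"), length(ctr), replace = TRUE)
        start0 <- ifelse(sgn == "+", ctr - half, ctr)
        gr <- GenomicRanges::GRanges(
          chromName,
          IRanges::IRanges(start = start0 + 1, width = readLength),
          strand = sgn)
        GenomeInfoDb::seqlengths(gr) <- chromSizes
        sort(gr)
      })
      names(out[[ab]]) <- grid$sample
    }
    out[["input"]] <- lapply(seq_len(nrow(grid)), function(s) {
      n <- rpois(1, inputDepth)
      start0 <- floor(runif(n, 0, genomeLen - readLength))
      sgn <- sample(c("+", "-"), n, replace = TRUE)
      gr <- GenomicRanges::GRanges(
        chromName, IRanges::IRanges(start = start0 + 1, width = readLength),
        strand = sgn)
      GenomeInfoDb::seqlengths(gr) <- chromSizes
      sort(gr)
    })
    names(out[["input"]]) <- grid$sample
  })
  out
}

#' Run the full simulator
#'
#' Convenience wrapper generating, from one master seed, the truth table,
#' FACS fractions, counts and latents, and the annotation. ChIP reads are
#' generated separately (they are only needed for a gene subset in most
#' analyses); see \code{\link{simulateChipReads}}.
#'
#' @inheritParams makeSyntheticTruth
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param model a \linkS4class{SynchronyModel}.
#' @param ... passed to \code{\link{makeSyntheticTruth}}.
#' @return list with truth, design, model, facs, counts, latents,
#'   librarySizes, annotation, chromSizes.
#' @examples
#' sim <- simulateCellCycle(nGenes = 50, seed = 1)
#' dim(sim$counts)
#' @export
simulateCellCycle <- function(nGenes = 1000, cyclicFrac = 0.1, seed = 1,
                              design = TimeCourseDesign(),
                              model = SynchronyModel(), ...) {
  truth <- makeSyntheticTruth(nGenes = nGenes, cyclicFrac = cyclicFrac,
                              seed = seed, ...)
  facs <- simulateSynchrony(model, design, seed = seed)
  expr <- simulateExpression(truth, facs, design, seed = seed)
  ann <- generateAnnotation(truth, seed = seed)
  c(list(truth = truth, design = design, model = model, facs = facs),
    expr, ann)
}
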