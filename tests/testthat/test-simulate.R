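test_that("flat genes stay flat and cyclic genes damp cycle over cycle", {
  sim <- mediumSim()
  tr <- sim$truth
  lat <- sim$latents
  flat <- tr$gene_id[!tr$cyclic][1:20]
  expect_true(all(apply(lat[flat, , drop = FALSE], 1,
                        function(x) diff(range(x))) < 1e-9))
  # peak-to-trough over the second cycle is smaller than over the first
  t1 <- paste0("Epi1_", c(0, 3, 6, 9, 12), "h")
  t2 <- paste0("Epi1_", c(12, 15, 18, 21, 24), "h")
  cyc <- tr$gene_id[tr$cyclic & tr$amplitude >= 1]
  r1 <- apply(lat[cyc, t1], 1, function(x) diff(range(x)))
  r2 <- apply(lat[cyc, t2], 1, function(x) diff(range(x)))
  expect_true(all(r2 < r1))
})

test_that("population latent matches the wrapped-normal closed form", {
  # independent oracle: E[cos(2pi(theta - psi))] under a wrapped normal
  # equals exp(-2 pi^2 sd^2) cos(2pi(mean - psi))
  sim <- mediumSim()
  tr <- sim$truth
  pos <- positionParams(sim$facs)
  g <- which(tr$cyclic)[1:5]
  for (i in g) {
    expected <- tr$baseline[i] + tr$amplitude[i] *
      exp(-2 * pi^2 * pos$sd^2) *
      cos(2 * pi * (pos$mean - tr$peak_phase[i]))
    got <- sim$latents[tr$gene_id[i], paste0("Epi1_", pos$time, "h")]
    expect_equal(unname(got), expected, tolerance = 1e-6)
  }
})

test_that("negative-binomial counts have the stated moments", {
  d <- defaultDesign()
  facs <- simulateSynchrony(SynchronyModel(), d, seed = 3)
  truth <- makeSyntheticTruth(nGenes = 1000, cyclicFrac = 0, seed = 3)
  truth$baseline <- 7; truth$dispersion <- 0.1
  libs <- stats::setNames(rep(1e6, 18), sampleGrid(d)$sample)
  ex <- simulateExpression(truth, facs, d, librarySizes = libs, seed = 3)
  m <- 2^7
  draws <- as.numeric(ex$counts[, 1])  # 1000 iid NB(mu = 128, phi = 0.1)
  se <- sqrt(m + 0.1 * m^2) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m), 3 * se)
  expect_error(simulateExpression(truth, facs, d,
                                  librarySizes = libs * 0, seed = 1),
               "positive")
})

test_that("annotation realizes the requested TSS layouts", {
  truth <- makeSyntheticTruth(nGenes = 6, cyclicFrac = 0, seed = 4)
  truth$n_tss <- c(1L, 1L, 2L, 2L, 3L, 1L)
  truth$tss_spacing <- c(0, 0, 6664, 6664, 600, 0)
  truth$neighbor_dist <- c(8000, 8000, 25000, 25000, 25000, 8000)
  ann <- generateAnnotation(truth, seed = 4)
  cat1 <- selectTss(ann$annotation)
  tab <- as.data.frame(tssTable(cat1))
  tab <- tab[match(truth$gene_id, tab$gene_id), ]
  expect_equal(tab$nTss, c(1, 1, 2, 2, 3, 1))
  expect_equal(tab$span, c(0, 0, 6664, 6664, 600, 0))
  # the two TSSs of the PCNA-like pair differ by exactly 6664
  g3 <- ann$annotation[ann$annotation$type == "transcript" &
                       ann$annotation$gene_id == truth$gene_id[3]]
  tss3 <- ifelse(as.character(GenomicRanges::strand(g3)) == "+",
                 GenomicRanges::start(g3) - 1, GenomicRanges::end(g3) - 1)
  expect_equal(abs(diff(sort(tss3))), 6664)
  # single-TSS genes requesting an 8 kb neighbor get one at exactly 8000
  grp <- classifyTssGroups(cat1)
  nd <- grp$nearestDist[match(truth$gene_id, grp$gene)]
  expect_equal(nd[c(1, 6)], c(8000, 8000))
  expect_true(all(nd[3:5] > 10000))
  expect_error(generateAnnotation(truth, genomeLength = 1e4, seed = 4),
               "fit")
})

test_that("emitted files round-trip to equal in-memory objects", {
  sim <- mediumSim()
  tmp <- withr::local_tempdir()
  # GTF
  gtf <- file.path(tmp, "ann.gtf")
  writeGtf(sim$annotation, gtf)
  back <- readGtf(gtf)
  asTable <- function(gr) {
    df <- data.frame(start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     type = as.character(gr$type),
                     gene_id = as.character(gr$gene_id),
                     transcript_id = as.character(gr$transcript_id))
    df[do.call(order, df), ]
  }
  expect_equal(asTable(back), asTable(sim$annotation),
               ignore_attr = TRUE)
  # counts and FACS TSV
  cf <- file.path(tmp, "counts.tsv")
  writeMatrixTsv(sim$counts, cf)
  expect_equal(readMatrixTsv(cf), sim$counts)
  ff <- file.path(tmp, "facs.tsv")
  writeFacsTsv(sim$facs, ff)
  expect_equal(readFacsTsv(ff), fractions(sim$facs), tolerance = 1e-12)
  # BED
  reads <- readsFromStarts(c(100, 250, 3999), c("+", "-", "+"), 20000)
  bf <- file.path(tmp, "reads.bed")
  writeBedReads(reads, bf)
  back <- readBedReads(bf)
  expect_equal(sort(GenomicRanges::start(back)),
               sort(GenomicRanges::start(reads)))
  expect_setequal(as.character(GenomicRanges::strand(back)),
                  as.character(GenomicRanges::strand(reads)))
  writeLines(c("chrT\t10\t85\t.\t0\t+", "chrT\tx\t85\t.\t0\t+"),
             file.path(tmp, "bad.bed"))
  expect_error(readBedReads(file.path(tmp, "bad.bed")), "line 2")
})

test_that("ChIP reads behave like Poisson placements around the TSS", {
  d <- TimeCourseDesign(timePoints = c(0, 3, 6, 9), replicates = "Epi1")
  truth <- makeSyntheticTruth(nGenes = 4, cyclicFrac = 0.5, seed = 6,
                              markersPerPhase = 0)
  truth$coupled <- FALSE  # uncoupled: time-constant intensity
  facs <- simulateSynchrony(SynchronyModel(), d, seed = 6)
  ex <- simulateExpression(truth, facs, d, seed = 6)
  ann <- generateAnnotation(truth, seed = 6)
  cat1 <- selectTss(ann$annotation)
  reads <- simulateChipReads(truth, ex$latents, cat1, d, ann$chromSizes,
                             antibodies = "polII", meanReadsPerGene = 400,
                             inputDepth = 50000, seed = 6)
  perSample <- vapply(reads$polII, length, 1L)
  # total reads per time point vary only by Poisson noise around 4*400
  chi <- sum((perSample - mean(perSample))^2) / mean(perSample)
  expect_gt(pchisq(chi, df = 3, lower.tail = FALSE), 0.01)
  # input track is uniform across bins (chi-square GOF at ~50k reads)
  inp <- reads$input[[1]]
  pos <- GenomicRanges::start(inp) - 1
  expect_gt(length(pos), 10000)
  bins <- cut(pos, breaks = seq(0, ann$chromSizes[[1]], length.out = 21),
              include.lowest = TRUE)
  o <- table(bins)
  chi2 <- sum((o - mean(o))^2 / mean(o))
  expect_gt(pchisq(chi2, df = 19, lower.tail = FALSE), 0.01)
  # doubling depth doubles expected read counts
  reads2 <- simulateChipReads(truth, ex$latents, cat1, d, ann$chromSizes,
                              antibodies = "polII", meanReadsPerGene = 800,
                              seed = 7)
  ratio <- mean(vapply(reads2$polII, length, 1L)) / mean(perSample)
  expect_lt(abs(ratio - 2), 0.15)
  expect_error(simulateChipReads(truth, ex$latents, cat1, d, ann$chromSizes,
                                 meanReadsPerGene = 0), "positive")
})
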