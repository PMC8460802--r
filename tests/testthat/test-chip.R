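test_that("the longest transcript's 5' end is the representative TSS", {
  tab <- as.data.frame(tssTable(selectTss(toyAnnotation())))
  expect_equal(tab$tss[tab$gene_id == "gPlus"], 7000)      # long variant
  expect_equal(tab$transcript_id[tab$gene_id == "gPlus"], "gPlus.t1")
  expect_equal(tab$tss[tab$gene_id == "gMinus"], 13000)    # 5' end = end
  expect_equal(tab$span[tab$gene_id == "gPlus"], 1500)
  # PCNA-like: the long variant wins even when the short one is expressed
  pcna <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = c(1001, 1001, 7665), end = c(17000, 17000, 11000)),
    strand = "+", type = c("gene", "transcript", "transcript"),
    gene_id = "PCNAlike", transcript_id = c(NA, "long", "short"))
  expect_equal(as.data.frame(tssTable(selectTss(pcna)))$transcript_id,
               "long")
  # equal spans: lower start wins, then lexicographic transcript id
  tie <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = c(100, 100, 200), end = c(1099, 1099, 1199)),
    strand = "+", type = c("gene", "transcript", "transcript"),
    gene_id = "tie", transcript_id = c(NA, "b", "a"))
  expect_equal(as.data.frame(tssTable(selectTss(tie)))$tss, 99)
  noTx <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 10),
    type = "gene", gene_id = "lonely", transcript_id = NA)
  expect_error(selectTss(noTx), "transcripts")
})

test_that("reads are extended from their 5' end and RPKM follows the formula", {
  cs <- c(chrT = 20000)
  # one + strand read at 0-based position 100 covers [100, 250)
  cov <- computeCoverage(readsFromStarts(100, "+", 20000), cs)
  covVec <- as.integer(cov$coverage[["chrT"]])
  expect_equal(which(covVec == 1), 101:250)
  # a - read with 5' end at 249 (0-based) also covers [100, 250)
  covM <- computeCoverage(readsFromStarts(175, "-", 20000), cs)
  expect_equal(which(as.integer(covM$coverage[["chrT"]]) == 1), 101:250)
  expect_equal(intervalRpkm(2, 50, 1e6), 40)
  # clipping at the chromosome end warns and counts
  expect_warning(covE <- computeCoverage(
    readsFromStarts(19950, "+", 20000), cs), "clipped")
  expect_equal(covE$clipped, 1)
})

test_that("TSS windows have 200 bins and TSS+75 sits in oriented bin 101", {
  cs <- c(chrT = 20000)
  catl <- selectTss(toyAnnotation())
  # + gene: a fragment midpoint at TSS + 75 = 7075 needs a + read at 7000
  bp <- binTssRegion(computeCoverage(readsFromStarts(7000, "+", 20000), cs),
                     catl)
  expect_equal(ncol(bp$counts), 200)
  expect_equal(unname(which(bp$counts["gPlus", ] == 1)), 102)  # 0-based 101
  # - gene: downstream point is TSS - 75 = 12925; a fragment centered
  # there comes from a + read starting at 12850
  bm <- binTssRegion(computeCoverage(readsFromStarts(12850, "+", 20000), cs),
                     catl)
  expect_equal(unname(which(bm$counts["gMinus", ] == 1)), 102)
  # tssSignal picks exactly that oriented bin
  norm <- matrix(0, 2, 200, dimnames = list(c("gPlus", "gMinus"), NULL))
  norm[, 102] <- 3
  expect_equal(unname(tssSignal(norm)), c(3, 3))
  uni <- matrix(0.7, 2, 200, dimnames = dimnames(norm))
  expect_equal(unname(tssSignal(uni)), c(0.7, 0.7))
  # a partial bin at the TSS point makes the signal missing
  info <- list(partial = matrix(FALSE, 2, 200, dimnames = dimnames(norm)))
  info$partial[1, 102] <- TRUE
  expect_true(is.na(tssSignal(norm, info)[1]) && !is.na(tssSignal(norm, info)[2]))
})

test_that("binned counts equal the brute-force per-base pileup oracle", {
  set.seed(19)
  cs <- c(chrT = 20000)
  catl <- selectTss(toyAnnotation())
  n <- 500
  starts <- sample(0:19924, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  bins <- binTssRegion(computeCoverage(readsFromStarts(starts, strands,
                                                       20000), cs), catl)
  tab <- as.data.frame(tssTable(catl))
  for (g in tab$gene_id) {
    oracle <- brutePileupBins(starts, strands, 20000,
                              tab$tss[tab$gene_id == g],
                              tab$strand[tab$gene_id == g])
    expect_identical(unname(bins$counts[g, ]), oracle)
  }
})

test_that("input normalization has log-ratio semantics", {
  flat <- function(x) list(rpkm = matrix(x, 2, 200,
    dimnames = list(c("gA", "gB"), NULL)))
  # chip == input (flat windows) -> exactly 0 in every bin
  expect_true(all(normalizeToInput(flat(5), list(flat(5))) == 0))
  # chip = 2x input, both >> pseudocount -> ~1.0
  expect_true(all(abs(normalizeToInput(flat(200), list(flat(100))) - 1)
                  < 0.01))
  # both zero -> 0 (pseudocount cancels)
  expect_true(all(normalizeToInput(flat(0), list(flat(0))) == 0))
  # mean input averages across input samples
  lr <- normalizeToInput(flat(150), list(flat(100), flat(200)))
  expect_true(all(abs(lr - log2(150.5 / 150.5)) < 1e-12))
  expect_error(normalizeToInput(flat(1), list()), "input")
})

test_that("duplicating all reads leaves normalized values unchanged", {
  cs <- c(chrT = 20000)
  catl <- selectTss(toyAnnotation())
  set.seed(21)
  cStarts <- sample(5000:15000, 800, replace = TRUE)
  iStarts <- sample(0:19924, 1200, replace = TRUE)
  mk <- function(st, times) readsFromStarts(rep(st, times),
                                            rep("+", length(st) * times),
                                            20000)
  n1 <- normalizeToInput(
    binTssRegion(computeCoverage(mk(cStarts, 1), cs), catl),
    list(binTssRegion(computeCoverage(mk(iStarts, 1), cs), catl)))
  n2 <- normalizeToInput(
    binTssRegion(computeCoverage(mk(cStarts, 2), cs), catl),
    list(binTssRegion(computeCoverage(mk(iStarts, 2), cs), catl)))
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("mirroring the genome and strands preserves oriented bin vectors", {
  L <- 20000
  cs <- c(chrT = L)
  ann <- toyAnnotation()
  # mirror: position p -> L - 1 - p (0-based); strands flip
  mirror <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = L + 1 - GenomicRanges::end(ann),
    end = L + 1 - GenomicRanges::start(ann)),
    strand = ifelse(as.character(GenomicRanges::strand(ann)) == "+",
                    "-", "+"),
    type = ann$type, gene_id = ann$gene_id,
    transcript_id = ann$transcript_id, gene_biotype = ann$gene_biotype)
  set.seed(22)
  starts <- sample(0:19924, 400, replace = TRUE)
  strands <- sample(c("+", "-"), 400, replace = TRUE)
  bins <- binTssRegion(computeCoverage(
    readsFromStarts(starts, strands, L), cs), selectTss(ann))
  # mirrored reads: fragment [s, s+150) maps to [L-s-150, L-s)
  fragStart <- ifelse(strands == "+", starts, starts + 75 - 150)
  mStarts <- ifelse(strands == "+", L - fragStart - 150 + 75, L - fragStart - 150)
  mStrands <- ifelse(strands == "+", "-", "+")
  mBins <- binTssRegion(computeCoverage(
    readsFromStarts(mStarts, mStrands, L), cs), selectTss(mirror))
  expect_identical(mBins$counts[rownames(bins$counts), ], bins$counts)
})

test_that("promoter marks need positive signal in two or more time points", {
  d <- defaultDesign()
  mkSignal <- function(posTimes, gene = "g1") {
    m <- matrix(-1, 1, 18, dimnames = list(gene, sampleNames(d)))
    for (t in posTimes) m[1, paste0(c("Epi1_", "Epi2_"), t, "h")] <- 1
    m
  }
  sig2 <- mkSignal(c(0, 3)); sig1 <- mkSignal(6); sig0 <- mkSignal(c())
  marks <- callPromoterMarks(list(polII = sig2, H3K4me3 = sig2,
                                  H3K27me3 = sig1), d)
  expect_true(marks$presence$polII)
  expect_true(marks$presence$H3K4me3)
  expect_false(marks$presence$H3K27me3)   # exactly 1 positive time point
  expect_true(marks$presence$bivalent == FALSE)
  marks2 <- callPromoterMarks(list(H3K4me3 = sig2, H3K27me3 = sig2), d)
  expect_true(marks2$presence$bivalent)   # K4 and K27 -> bivalent
  marksNeg <- callPromoterMarks(list(polII = sig0, H3K4me3 = sig0,
                                     H3K27me3 = sig0), d)
  expect_false(any(unlist(marksNeg$presence[, -1])))
})
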