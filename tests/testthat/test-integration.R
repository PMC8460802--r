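test_that("RNA-ChIP correlation pairs samples and drops exclusions", {
  d <- polIIExcludedDesign()
  sn <- sampleNames(d)
  rna <- matrix(rep(1:18, each = 2), 2, 18, byrow = FALSE,
                dimnames = list(c("g1", "g2"), sn))
  rna["g1", ] <- 1:18
  rna["g2", ] <- 1:18
  chip <- rna
  rec <- correlateRnaChip(rna, chip, d, assay = "polII")
  expect_equal(rec$rho, c(1, 1))
  expect_equal(rec$n, c(17, 17))  # (12 h, Epi2) dropped
  recAll <- correlateRnaChip(rna, chip, d, assay = NULL)
  expect_equal(recAll$n, c(18, 18))
  # brute-force rank correlation oracle on a 4-point profile
  d4 <- TimeCourseDesign(timePoints = c(0, 3, 6, 9), replicates = "Epi1")
  r4 <- matrix(c(1, 2, 3, 4), 1, 4,
               dimnames = list("g", sampleNames(d4)))
  c4 <- matrix(c(10, 30, 20, 40), 1, 4,
               dimnames = list("g", sampleNames(d4)))
  expect_equal(correlateRnaChip(r4, c4, d4)$rho, 0.8)
  # fewer than 4 pairs: missing rho, record still emitted
  c4[1, 1] <- NA
  rec4 <- correlateRnaChip(r4, c4, d4)
  expect_true(is.na(rec4$rho) && rec4$n == 3)
  expect_true(is.na(rec4$class))
})

test_that("correlation classes use strict 0.2 boundaries", {
  expect_equal(classifyCorrelation(c(0.47, 0.2, -0.2, -0.5, NA, 0.21)),
               c("high", "middle", "middle", "low", NA, "high"))
})

test_that("class pairs map onto the five groups as a partition", {
  cls <- c("high", "middle", "low")
  pairs <- expand.grid(pol = cls, k4 = cls, stringsAsFactors = FALSE)
  got <- correlationGroups(pairs$pol, pairs$k4)
  # enumerate all 9 class pairs against the five printed group definitions
  expected <- c("both_high", "k4_high", "k4_high",     # k4 = high
                "polII_high", "middle", "middle",      # k4 = middle
                "polII_high", "middle", "both_low")    # k4 = low
  expect_equal(got, expected)
  # spot checks from the stated precedence
  expect_equal(correlationGroups("high", "low"), "polII_high")
  expect_equal(correlationGroups("middle", "low"), "middle")
  expect_true(is.na(correlationGroups(NA, "high")))
  # every gene lands in exactly one group: it is a partition
  expect_false(anyNA(got))
  expect_setequal(unique(got),
                  c("both_high", "polII_high", "k4_high", "both_low",
                    "middle"))
})

test_that("phase comparisons use Welch t against S with Bonferroni over 4", {
  vals <- c(rep(1.5, 10), rep(1.5, 10), 1:10)
  names(vals) <- paste0("g", 1:30)
  phase <- rep(c("S", "G2", "M/G1"), each = 10)
  names(phase) <- names(vals)
  res <- phaseSignalComparison(vals, phase)
  g2row <- res$tests[res$tests$phase == "G2", ]
  expect_equal(g2row$t, 0)
  expect_equal(g2row$pAdj, 1)
  # hand-derived Welch for (1,2,3) vs (4,5,6)
  v2 <- c(1, 2, 3, 4, 5, 6); names(v2) <- paste0("h", 1:6)
  ph2 <- c(rep("G1/S", 3), rep("S", 3)); names(ph2) <- names(v2)
  res2 <- phaseSignalComparison(v2, ph2)
  row <- res2$tests[res2$tests$phase == "G1/S", ]
  expect_equal(row$t, -3.674, tolerance = 1e-3)
  expect_equal(row$df, 4, tolerance = 1e-6)
  expect_equal(row$pAdj, 4 * 0.021312, tolerance = 1e-4)
  # positivity filter: genes need signal > 0 in >= 2 time points
  prof <- matrix(-1, 30, 9, dimnames = list(names(vals), NULL))
  prof[1:22, 1:2] <- 1  # boundary: exactly 2 positive time points -> kept
  resF <- phaseSignalComparison(vals, phase, profile = prof, minPositive = 2)
  expect_equal(resF$nIncluded, 22)
  # a phase with < 2 genes is marked not computable
  expect_true(is.na(resF$tests$t[resF$tests$phase == "G2/M"]))
})

test_that("set-level correlation comparisons behave on degenerate input", {
  rho <- c(rep(0, 20), rep(0, 20), seq(-0.5, 0.5, length.out = 20))
  names(rho) <- paste0("g", 1:60)
  refs <- new("ReferenceSets", high = paste0("g", 21:40),
              low = paste0("g", 41:60), floor = 0, splitPoint = 0)
  res <- compareCorrelationSets(rho, paste0("g", 1:20), refs)
  cc <- res$sets[res$sets$set == "CC", ]
  expect_equal(cc$t, 0)
  expect_equal(cc$p, 1)
  # identical sets: pairwise p = 1
  pw <- res$pairwise[res$pairwise$setA == "CC" &
                     res$pairwise$setB == "!CC_high", ]
  expect_equal(pw$t, 0)
  expect_equal(pw$p, 1)
  expect_equal(unique(res$ecdf$set[res$ecdf$cumfrac == 1]),
               c("CC", "!CC_high", "!CC_low"))
})

test_that("correlation classes are invariant under monotone transforms", {
  d <- defaultDesign()
  set.seed(23)
  rna <- matrix(rnorm(5 * 18), 5, 18,
                dimnames = list(paste0("g", 1:5), sampleNames(d)))
  chip <- rna + matrix(rnorm(5 * 18, sd = 0.5), 5, 18)
  r1 <- correlateRnaChip(rna, chip, d)
  r2 <- correlateRnaChip(exp(rna), chip^3 + 2 * chip + 5, d)
  expect_equal(r2$rho, r1$rho, tolerance = 1e-12)
  expect_equal(r2$class, r1$class)
})

test_that("lncRNA candidates are cyclic lncRNAs ranked by correlation", {
  cyc <- c("l1", "l2", "l3", "p1")
  bio <- c(l1 = "lncRNA", l2 = "lncRNA", l3 = "lncRNA",
           p1 = "protein_coding", l4 = "lncRNA")
  mkRec <- function(genes, rho) data.frame(
    gene = genes, rho = rho, n = 18, class = classifyCorrelation(rho))
  pol <- mkRec(c("l1", "l2", "l3", "p1"), c(0.5, 0.9, 0.1, 0.8))
  k4 <- mkRec(c("l1", "l2", "l3", "p1"), c(0.4, 0.1, 0.1, 0.7))
  out <- selectLncrnaCandidates(cyc, bio, pol, k4)
  expect_equal(out$gene[1], "l1")          # both-high ranked first
  expect_equal(out$gene[2], "l2")          # then by max rho
  expect_false("p1" %in% out$gene)         # protein-coding excluded
  expect_false("l4" %in% out$gene)         # non-cyclic excluded
  expect_equal(out$highlyCorrelated, c(TRUE, TRUE, FALSE))
})
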