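#' Correlate RNA and ChIP profiles through the cycle
#'
#' For each gene, the per-sample (replicate x time point) RNA values are
#' paired with the ChIP TSS signals; samples excluded for the antibody's
#' assay, or missing in either profile, are dropped pairwise. Spearman's
#' rho uses average ranks for ties. Fewer than 4 pairs gives a missing
#' rho.
#'
#' @param rnaValues numeric matrix, genes x samples.
#' @param chipValues numeric matrix, genes x samples (scalar TSS signals).
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param assay antibody name whose exclusions apply (default NULL).
#' @return data.frame: gene, rho, n, class (see
#'   \code{\link{classifyCorrelation}}).
#' @export
correlateRnaChip <- function(rnaValues, chipValues, design, assay = NULL) {
  genes <- intersect(rownames(rnaValues), rownames(chipValues))
  drop <- excludedSamples(design, assay)
  samples <- setdiff(intersect(colnames(rnaValues), colnames(chipValues)),
                     drop)
  rho <- vapply(genes, function(g) {
    x <- rnaValues[g, samples]; y <- chipValues[g, samples]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4) return(c(NA_real_, sum(ok)))
    c(spearmanRho(x[ok], y[ok]), sum(ok))
  }, numeric(2))
  data.frame(gene = genes, rho = rho[1, ], n = as.integer(rho[2, ]),
             class = classifyCorrelation(rho[1, ]), row.names = NULL)
}

#' Classify a correlation value
#'
#' High is rho > 0.2, low is rho < -0.2, and everything between --
#' including the boundaries, since both inequalities are strict -- is
#' middle. Missing rho is unclassified (\code{NA}).
#'
#' @param rho numeric vector of Spearman correlations.
#' @return character vector: "high", "middle", "low" or NA.
#' @examples
#' classifyCorrelation(c(0.47, 0.2, -0.5))  # high, middle, low
#' @export
classifyCorrelation <- function(rho) {
  ifelse(is.na(rho), NA_character_,
         ifelse(rho > 0.2, "high", ifelse(rho < -0.2, "low", "middle")))
}

#' Five correlation groups from Pol II and H3K4me3 classes
#'
#' Genes are grouped by the pair of correlation classes with the
#' precedence: high for both; high for Pol II only; high for H3K4me3
#' only; low for both; otherwise middle. Genes missing either class are
#' ungrouped (\code{NA}). The groups plus ungrouped partition the input.
#'
#' @param polClass,k4Class character class vectors ("high"/"middle"/"low")
#'   aligned by gene.
#' @return character vector with levels both_high, polII_high, k4_high,
#'   both_low, middle.
#' @export
correlationGroups <- function(polClass, k4Class) {
  ifelse(is.na(polClass) | is.na(k4Class), NA_character_,
  ifelse(polClass == "high" & k4Class == "high", "both_high",
  ifelse(polClass == "high", "polII_high",
  ifelse(k4Class == "high", "k4_high",
  ifelse(polClass == "low" & k4Class == "low", "both_low", "middle")))))
}

#' Compare signal distributions across cell-cycle phases
#'
#' Welch's t-test of each phase group against the S-phase group, Bonferroni
#' corrected over the four phase-vs-S comparisons, plus a one-way ANOVA
#' across the five phase groups. For ChIP signals, genes enter only if
#' their per-time-point signal is positive in at least \code{minPositive}
#' time points.
#'
#' @param values named per-gene scalar values (e.g. mean expression or
#'   mean TSS signal across the cycle).
#' @param phase named per-gene phase labels (five levels).
#' @param profile optional genes x time points matrix used for the
#'   positivity filter; required when \code{minPositive} is not NULL.
#' @param minPositive minimum positive time points for inclusion (NULL to
#'   skip the filter; default NULL).
#' @return list with \code{tests} (data.frame phase, n, meanDiff, t, df,
#'   p, pAdj) and \code{anova} (F, df1, df2, p). A phase with fewer than 2
#'   genes is marked not computable (NA row).
#' @export
phaseSignalComparison <- function(values, phase, profile = NULL,
                                  minPositive = NULL) {
  genes <- names(values)[!is.na(values) & !is.na(phase[names(values)])]
  if (!is.null(minPositive)) {
    .assert(!is.null(profile), "positivity filter needs a profile matrix")
    npos <- rowSums(profile[genes, , drop = FALSE] > 0, na.rm = TRUE)
    genes <- genes[npos >= minPositive]
  }
  v <- values[genes]; ph <- phase[genes]
  sVals <- v[ph == "S"]
  others <- setdiff(phaseLevels(), "S")
  rows <- lapply(others, function(p) {
    g <- v[ph == p]
    if (length(g) < 2 || length(sVals) < 2)
      return(data.frame(phase = p, n = length(g), meanDiff = NA, t = NA,
                        df = NA, p = NA))
    w <- welchT(g, sVals)
    data.frame(phase = p, n = length(g), meanDiff = mean(g) - mean(sVals),
               t = w$statistic, df = w$df, p = w$p.value)
  })
  tests <- do.call(rbind, rows)
  tests$pAdj <- bonferroni(tests$p, m = length(others))
  groups <- split(v, factor(ph, levels = phaseLevels()))
  groups <- groups[vapply(groups, length, 1L) >= 2]
  av <- if (length(groups) >= 2) oneWayAnova(groups) else
    list(statistic = NA, df1 = NA, df2 = NA, p.value = NA)
  list(tests = tests, anova = av,
       nIncluded = length(genes))
}

#' Compare correlation distributions between gene sets
#'
#' For each of the cell-cycle (CC), !CC_high and !CC_low sets: the mean
#' rho with a one-sample t-test against zero; all pairwise two-tailed
#' unequal-variance t-tests between sets; and the cumulative distribution
#' of rho per set for plotting.
#'
#' @param rho named per-gene Spearman correlations.
#' @param cyclicSet character vector of cyclic gene ids.
#' @param refSets a \linkS4class{ReferenceSets}.
#' @return list with \code{sets} (set, n, meanRho, t, df, p),
#'   \code{pairwise} (setA, setB, t, df, p) and \code{ecdf} (data.frame
#'   set, rho, cumfrac).
#' @export
compareCorrelationSets <- function(rho, cyclicSet, refSets) {
  sets <- list(CC = cyclicSet, "!CC_high" = refHigh(refSets),
               "!CC_low" = refLow(refSets))
  vals <- lapply(sets, function(g) {
    x <- rho[intersect(g, names(rho))]
    x[!is.na(x)]
  })
  keep <- vapply(vals, length, 1L) >= 2
  if (!all(keep)) warning("empty or degenerate gene set skipped: ",
                          paste(names(vals)[!keep], collapse = ", "))
  vals <- vals[keep]
  setTab <- do.call(rbind, lapply(names(vals), function(nm) {
    tt <- oneSampleT(vals[[nm]], 0)
    data.frame(set = nm, n = length(vals[[nm]]), meanRho = mean(vals[[nm]]),
               t = tt$statistic, df = tt$df, p = tt$p.value)
  }))
  pairs <- utils::combn(names(vals), 2, simplify = FALSE)
  pairTab <- do.call(rbind, lapply(pairs, function(pr) {
    w <- welchT(vals[[pr[1]]], vals[[pr[2]]])
    data.frame(setA = pr[1], setB = pr[2], t = w$statistic, df = w$df,
               p = w$p.value)
  }))
  ec <- do.call(rbind, lapply(names(vals), function(nm) {
    x <- sort(vals[[nm]])
    data.frame(set = nm, rho = x, cumfrac = seq_along(x) / length(x))
  }))
  list(sets = setTab, pairwise = pairTab, ecdf = ec)
}

#' Select and rank candidate cell-cycle lncRNAs
#'
#' Cyclic genes of lncRNA biotype, flagged highly correlated when their
#' Pol II or H3K4me3 correlation class is high, and ranked with both-high
#' genes first, then by \code{max(rho_PolII, rho_K4)} descending.
#'
#' @param cyclicSet character vector of cyclic gene ids.
#' @param biotypes named per-gene biotype vector.
#' @param polRecords,k4Records data.frames from
#'   \code{\link{correlateRnaChip}} for Pol II and H3K4me3.
#' @param phases optional named phase labels to carry along.
#' @return data.frame: gene, cyclic, rho_polII, rho_k4, class_polII,
#'   class_k4, group, phase, highlyCorrelated, score; ordered by rank.
#' @export
selectLncrnaCandidates <- function(cyclicSet, biotypes, polRecords,
                                   k4Records, phases = NULL) {
  lnc <- cyclicSet[biotypes[cyclicSet] %in% "lncRNA"]
  pol <- polRecords[match(lnc, polRecords$gene), ]
  k4 <- k4Records[match(lnc, k4Records$gene), ]
  grp <- correlationGroups(pol$class, k4$class)
  out <- data.frame(
    gene = lnc, cyclic = TRUE,
    rho_polII = pol$rho, rho_k4 = k4$rho,
    class_polII = pol$class, class_k4 = k4$class, group = grp,
    phase = if (is.null(phases)) NA_character_ else
      unname(phases[lnc]),
    highlyCorrelated = (pol$class %in% "high") | (k4$class %in% "high"),
    score = pmax(pol$rho, k4$rho, na.rm = TRUE), row.names = NULL)
  out[order(!(out$group %in% "both_high"), -out$score), , drop = FALSE]
}
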