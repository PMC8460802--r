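#' @importFrom mclust Mclust mclustBIC
NULL

#' Fit PLS regression of expression on FACS phase fractions
#'
#' NIPALS PLS2 with the FACS phase-fraction matrix as the response.
#' Gene (X) columns are centered and scaled by the square root of their
#' mean precision weight (normalized to unit mean) when weights are
#' supplied; response columns are centered. The per-gene variable
#' importance in projection (VIP) is computed from the X-weights and the
#' per-component explained response sum of squares; squared VIP averages
#' to one across genes, and constant gene columns receive VIP 0.
#'
#' @param X numeric matrix, samples x genes (row names = sample names).
#' @param Y numeric matrix, samples x responses, rows aligned with X.
#' @param ncomp number of components (default 3, matching a G1/S/G2M
#'   response).
#' @param geneWeights optional per-gene mean precision weights (positive),
#'   e.g. row means of \code{voomTransform(counts)$weights}.
#' @param tol,maxIter NIPALS convergence controls.
#' @return A \linkS4class{PlsResult} with VIP, X-weights, Y-loadings and
#'   explained-Y components (no permutation p-values).
#' @examples
#' X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("g", 1:6)))
#' Y <- matrix(rnorm(30), 10, 3)
#' vipScores(fitPls(X, Y, ncomp = 2))
#' @export
fitPls <- function(X, Y, ncomp = 3, geneWeights = NULL,
                   tol = 1e-10, maxIter = 200) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  .assert(nrow(X) == nrow(Y), "X and Y must have aligned rows")
  .assert(ncomp >= 1, "ncomp must be >= 1")
  if (ncomp > min(nrow(X) - 1, ncol(X)))
    stop("n_components exceeds the rank of the predictor matrix",
         call. = FALSE)
  genes <- colnames(X)
  if (is.null(genes)) genes <- paste0("V", seq_len(ncol(X)))
  E <- scale(X, center = TRUE, scale = FALSE)
  if (!is.null(geneWeights)) {
    .assert(length(geneWeights) == ncol(X) && all(geneWeights > 0),
            "geneWeights must be positive, one per gene")
    E <- sweep(E, 2, sqrt(geneWeights / mean(geneWeights)), `*`)
  }
  F <- scale(Y, center = TRUE, scale = FALSE)
  p <- ncol(E)
  W <- matrix(0, p, ncomp, dimnames = list(genes, NULL))
  Q <- matrix(0, ncol(F), ncomp, dimnames = list(colnames(Y), NULL))
  ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- F[, which.max(apply(F, 2, stats::var))]
    if (all(abs(u) < 1e-300)) u <- rnorm(nrow(F))
    tOld <- NULL
    for (it in seq_len(maxIter)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14)
        stop("n_components exceeds the rank of the predictor matrix",
             call. = FALSE)
      w <- w / nw
      tt <- drop(E %*% w)
      q <- drop(crossprod(F, tt)) / sum(tt^2)
      if (sum(q^2) < 1e-300) break
      u <- drop(F %*% q) / sum(q^2)
      if (!is.null(tOld) &&
          sum((tt - tOld)^2) < tol^2 * sum(tt^2)) break
      tOld <- tt
    }
    pl <- drop(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pl)
    F <- F - tcrossprod(tt, q)
    W[, a] <- w
    Q[, a] <- q
    ssy[a] <- sum(tt^2) * sum(q^2)
  }
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- genes
  new("PlsResult", ncomp = as.integer(ncomp), vip = vip, weights = W,
      yloadings = Q, explainedY = ssy, pvalue = numeric(),
      qvalue = numeric(), cyclic = character(), qThreshold = NA_real_)
}

# Permute time-point labels within each replicate, the same permutation in
# every replicate, preserving the design's replicate pairing. Returns the
# row permutation of the sample grid.
.designPermutation <- function(grid, timePoints) {
  perm <- sample(length(timePoints))
  newTime <- timePoints[perm][match(grid$time, timePoints)]
  match(paste0(grid$replicate, "_", newTime, "h"), grid$sample)
}

# Per-gene explained variance on the response space: squared multiple
# correlation of each centered gene column with [1, Y]. Constant genes
# get 0, not NaN.
.projectionStat <- function(Xc, tss, Y) {
  Q <- qr.Q(qr(cbind(1, Y)))
  out <- colSums(crossprod(Q, Xc)^2) / tss
  out[tss < 1e-12] <- 0
  out
}

#' Permutation significance of per-gene cell-cycle dependence
#'
#' Builds a per-gene null distribution by permuting the response rows with
#' design-respecting permutations: time-point labels are shuffled within
#' each replicate, the same shuffle applied to all replicates so the
#' replicate pairing survives. Per-gene p-values are
#' \code{(1 + #(null >= observed)) / (1 + nPerm)} (ties counted
#' conservatively), followed by Benjamini--Hochberg adjustment; the cyclic
#' set is all genes with q at or below the threshold.
#'
#' The per-gene statistic is pluggable. The default, \code{"projection"},
#' is each gene's explained variance on the response space (the squared
#' multiple correlation of the gene profile with the FACS fractions):
#' under permutation its null reflects only how well a scrambled phase
#' ordering fits the gene, which is what the test asks. The alternative,
#' \code{"vip"}, permutes the joint-fit VIP itself; because VIP is a
#' relative, variance-driven score, high-variance genes keep elevated VIP
#' under permuted responses and the per-gene null loses most of its
#' discriminating power (see the package vignette). The fitted VIP is
#' reported in either case.
#'
#' @inheritParams fitPls
#' @param design a \linkS4class{TimeCourseDesign}; X and Y rows must be
#'   named/aligned to its samples.
#' @param nPerm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @param qThreshold BH q cutoff for the cyclic call (default 0.05).
#' @param statistic per-gene statistic: \code{"projection"} (default) or
#'   \code{"vip"}.
#' @return A \linkS4class{PlsResult} with p-values, q-values and the
#'   cyclic gene set.
#' @export
geneSignificance <- function(X, Y, design, ncomp = 3, nPerm = 999, seed = 1,
                             qThreshold = 0.05, geneWeights = NULL,
                             statistic = c("projection", "vip")) {
  statistic <- match.arg(statistic)
  .assert(nPerm >= 99,
          "n_perm < 99 gives too little resolution for q <= 0.05")
  grid <- sampleGrid(design)
  X <- as.matrix(X)
  .assert(!is.null(rownames(X)) && all(grid$sample %in% rownames(X)),
          "X rows must be named by design samples")
  X <- X[grid$sample, , drop = FALSE]
  Y <- as.matrix(Y)[grid$sample, , drop = FALSE]
  if (statistic == "projection") {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    tss <- colSums(Xc^2)
    stat <- function(Yp) .projectionStat(Xc, tss, Yp)
  } else {
    stat <- function(Yp) vipScores(fitPls(X, Yp, ncomp = ncomp,
                                          geneWeights = geneWeights))
  }
  obs <- stat(Y)
  cnt <- numeric(length(obs))
  .withSeed(.subSeed(seed, "permutation"), {
    for (b in seq_len(nPerm)) {
      idx <- .designPermutation(grid, design@timePoints)
      cnt <- cnt + (stat(Y[idx, , drop = FALSE]) >= obs)
    }
  })
  pv <- (1 + cnt) / (1 + nPerm)
  names(pv) <- colnames(X)
  qv <- stats::p.adjust(pv, method = "BH")
  fit <- fitPls(X, Y, ncomp = ncomp, geneWeights = geneWeights)
  new("PlsResult", ncomp = fit@ncomp, vip = fit@vip, weights = fit@weights,
      yloadings = fit@yloadings, explainedY = fit@explainedY,
      pvalue = pv, qvalue = qv,
      cyclic = names(qv)[qv <= qThreshold], qThreshold = qThreshold)
}

#' Define the non-cyclic reference gene sets
#'
#' Non-cyclic genes expressed at least as highly as the least-expressed
#' cyclic gene form the eligible pool; their mean log expression is
#' bimodal, and a two-component Gaussian mixture (unequal variances)
#' splits them into a highly expressed (!CC_high) and a lowly expressed
#' (!CC_low) reference set by posterior >= 0.5.
#'
#' @param meanExpr named per-gene mean log2 expression.
#' @param cyclicSet character vector of cyclic gene ids.
#' @return A \linkS4class{ReferenceSets}. With a degenerate (single-mode)
#'   eligible pool a single high set is returned with a warning.
#' @export
defineReferenceSets <- function(meanExpr, cyclicSet) {
  .assert(!is.null(names(meanExpr)), "meanExpr must be named by gene")
  .assert(all(cyclicSet %in% names(meanExpr)),
          "cyclic genes must appear in meanExpr")
  floorVal <- min(meanExpr[cyclicSet])
  eligible <- meanExpr[!(names(meanExpr) %in% cyclicSet)]
  eligible <- eligible[eligible >= floorVal]
  if (length(eligible) < 10)
    stop("fewer than 10 eligible reference genes", call. = FALSE)
  if (stats::sd(eligible) < 1e-8) {
    warning("degenerate expression distribution; single reference set")
    return(new("ReferenceSets", high = names(eligible), low = character(),
               floor = floorVal, splitPoint = NA_real_))
  }
  fit <- tryCatch(
    Mclust(as.numeric(eligible), G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture fit degenerate; single reference set")
    return(new("ReferenceSets", high = names(eligible), low = character(),
               floor = floorVal, splitPoint = NA_real_))
  }
  hiComp <- which.max(fit$parameters$mean)
  isHigh <- fit$z[, hiComp] >= 0.5
  high <- names(eligible)[isHigh]
  low <- names(eligible)[!isHigh]
  split <- if (length(high) && length(low))
    mean(fit$parameters$mean) else NA_real_
  new("ReferenceSets", high = high, low = low,
      floor = floorVal, splitPoint = split)
}
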