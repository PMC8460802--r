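#' Remove genes with a zero count in any sample
#'
#' Genes with a zero count anywhere in the time course are stripped before
#' modelling, preventing on/off genes from dominating the PLS fit. Order
#' is preserved; an empty result is allowed.
#'
#' @param counts integer matrix, genes x samples.
#' @return the filtered matrix.
#' @examples
#' m <- rbind(a = c(5, 0, 7), b = c(1, 2, 3))
#' rownames(filterZeroCount(m))  # "b"
#' @export
filterZeroCount <- function(counts) {
  .assert(all(counts >= 0), "counts must be nonnegative")
  keep <- rowSums(counts == 0) == 0
  counts[keep, , drop = FALSE]
}

#' Precision-weighted log-CPM transform
#'
#' Transforms counts to \code{log2((count + 0.5) / (libsize + 1) * 1e6)}
#' and attaches per-observation precision weights from a locally weighted
#' mean--variance trend (sqrt residual standard deviation against average
#' log2 count), as implemented by \code{limma::voom}; weights are the
#' predicted standard deviation to the power -4, with the trend clipped at
#' its boundary at the extremes. An intercept-only design is used: the
#' downstream PLS fit consumes the weights, not a linear-model fit.
#'
#' @param counts integer matrix, genes x samples (>= 2 samples).
#' @param span smoother span (default 0.5).
#' @return a \code{limma} \code{EList} with components \code{E} (values),
#'   \code{weights}, and the fitted trend in \code{voom.xy}/\code{voom.line}.
#' @examples
#' m <- matrix(rpois(60, 50), 10, 6,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' v <- voomTransform(m)
#' stopifnot(all(v$weights > 0))
#' @export
voomTransform <- function(counts, span = 0.5) {
  .assert(ncol(counts) >= 2, "need at least 2 samples for a residual sd")
  tryCatch(limma::voom(counts, design = NULL, span = span, save.plot = TRUE),
           error = function(e) {
             # degenerate mean-variance trend (fewer than two distinct
             # abundances): flat trend, uniform weights
             lib <- colSums(counts)
             E <- t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
             s <- sqrt(mean(apply(E, 1, stats::var)))
             w <- if (is.finite(s) && s > 0) s^-4 else 1
             methods::new("EList", list(E = E,
               weights = matrix(w, nrow(E), ncol(E),
                                dimnames = dimnames(E))))
           })
}

#' Per-time-point mean profiles
#'
#' Averages values over replicates at each time point, skipping samples
#' excluded for the named assay. A time point whose replicates are all
#' excluded (or missing) is reported as \code{NA}, never zero.
#'
#' @param values numeric matrix, genes x samples (sample names as produced
#'   by \code{\link{sampleNames}}).
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param assay assay name whose exclusions apply (default \code{NULL}:
#'   no exclusions).
#' @return numeric matrix, genes x time points (columns \code{<hours>h}).
#' @export
meanProfile <- function(values, design, assay = NULL) {
  grid <- sampleGrid(design)
  drop <- excludedSamples(design, assay)
  use <- grid[!(grid$sample %in% drop) & grid$sample %in% colnames(values), ,
              drop = FALSE]
  out <- vapply(design@timePoints, function(tp) {
    s <- use$sample[use$time == tp]
    if (length(s) == 0) return(rep(NA_real_, nrow(values)))
    rowMeans(values[, s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(values)))
  out <- matrix(out, nrow = nrow(values))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(values), paste0(design@timePoints, "h"))
  out
}
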