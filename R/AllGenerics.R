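#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL

#' Sample names of a design
#'
#' @param object a \linkS4class{TimeCourseDesign}.
#' @param ... unused.
#' @return Character vector \code{<replicate>_<hours>h}, replicate-major.
#' @export
setGeneric("sampleNames", function(object, ...) standardGeneric("sampleNames"))

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "TimeCourseDesign", function(object, ...) {
  grid <- sampleGrid(object)
  paste0(grid$replicate, "_", grid$time, "h")
})

#' Design cells as a data.frame
#'
#' @param design a \linkS4class{TimeCourseDesign}.
#' @return data.frame with columns \code{replicate}, \code{time},
#'   \code{sample}, replicate-major order.
#' @export
sampleGrid <- function(design) {
  grid <- expand.grid(time = design@timePoints,
                      replicate = design@replicates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("replicate", "time")]
  grid$sample <- paste0(grid$replicate, "_", grid$time, "h")
  grid
}

#' Time points of a design
#' @param design a \linkS4class{TimeCourseDesign}.
#' @return numeric vector of hours.
#' @export
timePoints <- function(design) design@timePoints

#' Replicate labels of a design
#' @param design a \linkS4class{TimeCourseDesign}.
#' @return character vector.
#' @export
replicates <- function(design) design@replicates

#' Samples excluded for an assay
#'
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param assay assay name (e.g. \code{"polII"}); \code{NULL} returns none.
#' @return character vector of excluded sample names.
#' @export
excludedSamples <- function(design, assay = NULL) {
  ex <- design@excluded
  if (is.null(assay) || nrow(ex) == 0) return(character())
  ex <- ex[ex$assay == assay, , drop = FALSE]
  if (nrow(ex) == 0) return(character())
  paste0(ex$replicate, "_", ex$time, "h")
}

#' Phase fractions matrix
#' @param object a \linkS4class{FacsFractions}.
#' @return numeric matrix, samples x c(G1, S, G2M).
#' @export
fractions <- function(object) object@fractions

#' Wrapped-normal position parameters per time point
#' @param object a \linkS4class{FacsFractions}.
#' @return data.frame with columns time, mean, sd.
#' @export
positionParams <- function(object) object@positions

#' Per-gene VIP scores
#' @param object a \linkS4class{PlsResult}.
#' @return named numeric vector.
#' @export
vipScores <- function(object) object@vip

#' Cyclic gene set of a PLS result
#' @param object a \linkS4class{PlsResult}.
#' @return character vector of gene ids with q below the threshold.
#' @export
cyclicGenes <- function(object) object@cyclic

#' Permutation p- and q-values of a PLS result
#' @param object a \linkS4class{PlsResult}.
#' @return data.frame gene, vip, pvalue, qvalue, cyclic.
#' @export
geneTable <- function(object) {
  data.frame(gene = names(object@vip), vip = unname(object@vip),
             pvalue = if (length(object@pvalue)) unname(object@pvalue) else NA,
             qvalue = if (length(object@qvalue)) unname(object@qvalue) else NA,
             cyclic = names(object@vip) %in% object@cyclic,
             row.names = NULL)
}

#' Representative-TSS table of a catalog
#' @param object a \linkS4class{TssCatalog}.
#' @return DataFrame, one row per gene.
#' @export
tssTable <- function(object) object@genes

#' Reference set accessors
#' @param object a \linkS4class{ReferenceSets}.
#' @return character vector of gene ids.
#' @export
refHigh <- function(object) object@high

#' @rdname refHigh
#' @export
refLow <- function(object) object@low

setMethod("show", "TimeCourseDesign", function(object) {
  cat("TimeCourseDesign:", length(object@replicates), "replicate(s) x",
      length(object@timePoints), "time points (",
      min(object@timePoints), "-", max(object@timePoints), "h )\n")
  if (nrow(object@excluded))
    cat("  excluded:",
        paste(sprintf("%s(%s,%gh)", object@excluded$assay,
                      object@excluded$replicate, object@excluded$time),
              collapse = ", "), "\n")
})

setMethod("show", "SynchronyModel", function(object) {
  cat(sprintf(paste0("SynchronyModel: cycle %.3g h, release at %.3g,",
                     " sigma0 %.3g, kappa %.3g /h\n"),
              object@cycleLength, object@releasePosition,
              object@sigma0, object@kappa))
  arcs <- vapply(object@phaseIntervals,
                 function(a) sprintf("[%.2f,%.2f)", a[1], a[2]), "")
  cat("  arcs:", paste(names(arcs), arcs, sep = "=", collapse = " "), "\n")
})

setMethod("show", "FacsFractions", function(object) {
  cat("FacsFractions:", nrow(object@fractions), "samples\n")
  print(head(round(object@fractions, 3), 4))
  if (nrow(object@fractions) > 4) cat("  ...\n")
})

setMethod("show", "PlsResult", function(object) {
  cat("PlsResult:", length(object@vip), "genes,", object@ncomp,
      "components\n")
  if (length(object@pvalue))
    cat("  cyclic genes (q <=", object@qThreshold, "):",
        length(object@cyclic), "\n")
  else cat("  (no permutation test run)\n")
})

setMethod("show", "TssCatalog", function(object) {
  cat("TssCatalog:", nrow(object@genes), "genes,",
      nrow(object@allTss), "distinct TSSs\n")
})

setMethod("show", "ReferenceSets", function(object) {
  cat("ReferenceSets: !CC_high n =", length(object@high),
      ", !CC_low n =", length(object@low),
      sprintf("(floor %.3g, split %.3g)\n", object@floor, object@splitPoint))
})
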