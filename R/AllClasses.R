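#' Time-course design of a synchronization experiment
#'
#' Samples are the cells of (replicate x time point); every expression or
#' ChIP profile in the package is indexed by these cells. Sample names are
#' \code{<replicate>_<hours>h} (e.g. \code{Epi1_12h}). An exclusion list
#' records (assay, replicate, time) cells dropped from downstream analysis
#' of a named assay, such as a failed ChIP library.
#'
#' @slot timePoints numeric, strictly increasing, hours after release.
#' @slot replicates character replicate labels.
#' @slot excluded data.frame with columns \code{assay}, \code{replicate},
#'   \code{time}; may have zero rows.
#' @export
setClass("TimeCourseDesign",
  representation(timePoints = "numeric", replicates = "character",
                 excluded = "data.frame"),
  validity = function(object) {
    msg <- NULL
    tp <- object@timePoints
    if (length(tp) < 2 || any(diff(tp) <= 0))
      msg <- c(msg, "timePoints must be strictly increasing (length >= 2)")
    if (length(object@replicates) < 1 || anyDuplicated(object@replicates))
      msg <- c(msg, "replicates must be unique labels")
    ex <- object@excluded
    if (!all(c("assay", "replicate", "time") %in% colnames(ex)))
      msg <- c(msg, "excluded needs columns assay, replicate, time")
    else if (nrow(ex) > 0 &&
             (!all(ex$replicate %in% object@replicates) ||
              !all(ex$time %in% tp)))
      msg <- c(msg, "excluded samples must reference existing design cells")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a time-course design
#'
#' Defaults reproduce a double-thymidine-block release time course: samples
#' every 3 h for 24 h in two independent experiments (Epi1, Epi2).
#'
#' @param timePoints hours after release (default \code{seq(0, 24, by = 3)}).
#' @param replicates replicate labels (default \code{c("Epi1", "Epi2")}).
#' @param excluded data.frame of (assay, replicate, time) exclusions; the
#'   conventional exclusion for a failed Pol II library is
#'   \code{data.frame(assay = "polII", replicate = "Epi2", time = 12)}.
#' @return A \linkS4class{TimeCourseDesign}.
#' @examples
#' d <- TimeCourseDesign()
#' sampleNames(d)
#' @export
TimeCourseDesign <- function(timePoints = seq(0, 24, by = 3),
                             replicates = c("Epi1", "Epi2"),
                             excluded = data.frame(assay = character(),
                                                   replicate = character(),
                                                   time = numeric())) {
  new("TimeCourseDesign", timePoints = as.numeric(timePoints),
      replicates = as.character(replicates), excluded = excluded)
}

#' Wrapped-normal synchrony model of a released cell population
#'
#' Cell-cycle position lives on the circle [0, 1). At time t after release
#' the population position is wrapped normal with mean
#' \code{releasePosition + t / cycleLength} and standard deviation
#' \code{sqrt(sigma0^2 + (kappa * t)^2)}, so synchrony decays monotonically.
#' Phase fractions are the wrapped-normal mass over the G1/S/G2M arcs.
#'
#' @slot cycleLength hours per cycle.
#' @slot releasePosition cycle fraction in [0,1) where cells sit at t = 0
#'   (the G1/S boundary for a double thymidine block).
#' @slot sigma0 initial position dispersion, cycle-fraction units.
#' @slot kappa dispersion growth, cycle fraction per hour.
#' @slot phaseIntervals named list of \code{c(start, end)} arcs for
#'   G1, S, G2M; disjoint, covering [0,1).
#' @export
setClass("SynchronyModel",
  representation(cycleLength = "numeric", releasePosition = "numeric",
                 sigma0 = "numeric", kappa = "numeric",
                 phaseIntervals = "list"),
  validity = function(object) {
    msg <- NULL
    if (object@cycleLength <= 0) msg <- c(msg, "cycleLength must be > 0")
    if (object@sigma0 < 0 || object@kappa < 0)
      msg <- c(msg, "dispersion parameters must be nonnegative")
    if (object@releasePosition < 0 || object@releasePosition >= 1)
      msg <- c(msg, "releasePosition must lie in [0,1)")
    ph <- object@phaseIntervals
    if (!setequal(names(ph), c("G1", "S", "G2M")))
      msg <- c(msg, "phaseIntervals must name exactly G1, S, G2M")
    else {
      arcs <- do.call(rbind, ph)
      o <- order(arcs[, 1])
      arcs <- arcs[o, , drop = FALSE]
      if (any(arcs[, 2] <= arcs[, 1]) ||
          any(abs(arcs[-nrow(arcs), 2] - arcs[-1, 1]) > 1e-9) ||
          abs(arcs[1, 1]) > 1e-9 || abs(arcs[nrow(arcs), 2] - 1) > 1e-9)
        msg <- c(msg, "phase arcs must be disjoint and cover [0,1)")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a synchrony model
#'
#' Defaults are calibrated so that, with release at the G1/S boundary and a
#' 14 h cycle, about 90\% of cells pass synchronously through the first
#' S phase and about 70\% through the second, matching the behaviour of a
#' double-thymidine-block release monitored by FACS.
#'
#' @param cycleLength hours per cycle (default 14).
#' @param releasePosition position at release, default 0 (the G1/S boundary,
#'   i.e. the start of the S arc).
#' @param sigma0 initial dispersion in cycle fractions (default 0.095).
#' @param kappa dispersion growth per hour (default 0.0049).
#' @param phaseIntervals arcs for S, G2M, G1; defaults 0.35/0.25/0.40 of
#'   the cycle starting at S.
#' @return A \linkS4class{SynchronyModel}.
#' @export
SynchronyModel <- function(cycleLength = 14, releasePosition = 0,
                           sigma0 = 0.095, kappa = 0.0049,
                           phaseIntervals = list(S = c(0, 0.35),
                                                 G2M = c(0.35, 0.60),
                                                 G1 = c(0.60, 1))) {
  new("SynchronyModel", cycleLength = cycleLength,
      releasePosition = releasePosition, sigma0 = sigma0, kappa = kappa,
      phaseIntervals = phaseIntervals)
}

#' FACS phase fractions with the underlying position distributions
#'
#' Rows are samples (replicate x time point); columns are the fractions of
#' cells in G1, S and G2M, each row summing to one. The per-time-point
#' wrapped-normal position parameters used to generate the fractions are
#' kept so that expression simulation can integrate over the same
#' distribution.
#'
#' @slot fractions numeric matrix, samples x c(G1, S, G2M).
#' @slot positions data.frame with columns \code{time}, \code{mean},
#'   \code{sd} (cycle-fraction units).
#' @export
setClass("FacsFractions",
  representation(fractions = "matrix", positions = "data.frame"),
  validity = function(object) {
    f <- object@fractions
    if (!identical(colnames(f), c("G1", "S", "G2M")))
      return("fraction columns must be G1, S, G2M")
    if (any(f < 0)) return("fractions must be nonnegative")
    if (any(abs(rowSums(f) - 1) > 1e-9))
      return("each fraction row must sum to 1 within 1e-9")
    TRUE
  })

#' Catalog of representative transcription start sites
#'
#' One representative TSS per gene, taken from the gene's longest transcript
#' (maximal genomic span; ties broken by lowest start, then transcript id).
#' All distinct transcript TSSs are kept so that multi-TSS span (maximum
#' pairwise distance) and TSS-arrangement groups can be computed.
#' Coordinates are 0-based.
#'
#' @slot genes DataFrame: gene_id, chrom, tss (0-based), strand,
#'   transcript_id, nTss (distinct TSS count), span (max pairwise distance),
#'   biotype.
#' @slot allTss DataFrame: gene_id, chrom, tss, strand.
#' @export
setClass("TssCatalog",
  representation(genes = "DataFrame", allTss = "DataFrame"),
  validity = function(object) {
    g <- object@genes
    need <- c("gene_id", "chrom", "tss", "strand", "transcript_id",
              "nTss", "span")
    if (!all(need %in% colnames(g)))
      return(paste("genes needs columns:", paste(need, collapse = ", ")))
    if (any(g$span < 0)) return("multi-TSS span must be >= 0")
    TRUE
  })

#' Result of a PLS fit against FACS phase fractions
#'
#' Holds the per-gene variable importance in projection (VIP), and, after
#' permutation testing, per-gene p-values, BH q-values and the cyclic gene
#' set at the configured q threshold.
#'
#' @slot ncomp number of PLS components.
#' @slot vip named numeric, per-gene VIP (mean of squared VIP equals 1).
#' @slot weights genes x ncomp X-weight matrix (unit columns).
#' @slot yloadings response-loading matrix (Y columns x ncomp).
#' @slot explainedY per-component explained Y sum of squares.
#' @slot pvalue named numeric permutation p-values (empty before testing).
#' @slot qvalue named numeric BH q-values.
#' @slot cyclic character vector of cyclic gene ids.
#' @slot qThreshold numeric threshold used for the cyclic call.
#' @export
setClass("PlsResult",
  representation(ncomp = "integer", vip = "numeric", weights = "matrix",
                 yloadings = "matrix", explainedY = "numeric",
                 pvalue = "numeric", qvalue = "numeric",
                 cyclic = "character", qThreshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@vip < 0)) msg <- c(msg, "VIP must be nonnegative")
    if (length(object@vip) &&
        abs(mean(object@vip^2) - 1) > 1e-6)
      msg <- c(msg, "mean squared VIP must equal 1")
    if (length(object@pvalue) &&
        (any(object@pvalue <= 0) || any(object@pvalue > 1)))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if (length(object@cyclic) &&
        !all(object@cyclic %in% names(object@vip)))
      msg <- c(msg, "cyclic set must be a subset of analyzed genes")
    if (is.null(msg)) TRUE else msg
  })

#' Non-cyclic reference gene sets split by expression level
#'
#' Genes without a cell-cycle-dependent profile but with mean expression at
#' least that of the least-expressed cyclic gene, split at the boundary of
#' a bimodal expression distribution into a highly expressed (!CC_high) and
#' a lowly expressed (!CC_low) reference set.
#'
#' @slot high character, !CC_high gene ids.
#' @slot low character, !CC_low gene ids.
#' @slot floor minimum-mean-expression floor (from the cyclic set).
#' @slot splitPoint expression value separating the two modes.
#' @export
setClass("ReferenceSets",
  representation(high = "character", low = "character",
                 floor = "numeric", splitPoint = "numeric"),
  validity = function(object) {
    if (length(intersect(object@high, object@low)))
      return("!CC_high and !CC_low must be disjoint")
    TRUE
  })
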