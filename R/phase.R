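#' Mean profiles of known phase-marker genes
#'
#' Each marker gene's per-time-point mean profile is z-scored gene-wise
#' and the z-scored profiles are averaged within each phase, giving one
#' template profile per phase label.
#'
#' @param values numeric matrix, genes x samples.
#' @param markers named list mapping each phase label (G1/S, S, G2, G2/M,
#'   M/G1) to marker gene ids; markers absent from \code{values} are
#'   dropped (a phase left with none is an error; fewer than 3 gives a
#'   warning).
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param assay exclusions to honor (default none).
#' @return numeric matrix, phases x time points.
#' @export
buildMarkerProfiles <- function(values, markers, design, assay = NULL) {
  .assert(setequal(names(markers), phaseLevels()),
          "markers must name exactly the five phase labels")
  prof <- meanProfile(values, design, assay)
  out <- t(vapply(phaseLevels(), function(ph) {
    ids <- intersect(markers[[ph]], rownames(prof))
    if (length(ids) == 0)
      stop("no markers detected for phase ", ph, call. = FALSE)
    if (length(ids) < 3)
      warning("fewer than 3 markers detected for phase ", ph)
    z <- t(apply(prof[ids, , drop = FALSE], 1, .zscore))
    colMeans(z)
  }, numeric(ncol(prof))))
  dimnames(out) <- list(phaseLevels(), colnames(prof))
  out
}

.zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Assign cyclic genes to cell-cycle phases
#'
#' Correlates each gene's z-scored per-time-point mean profile with the
#' five phase templates (Pearson) and assigns the phase with the largest
#' correlation; ties are broken in the fixed order G1/S, S, G2, G2/M,
#' M/G1. Genes with a constant profile are flagged unassignable
#' (phase \code{NA}); all five correlations are always reported.
#'
#' @param values numeric matrix, genes x samples (typically restricted to
#'   the cyclic set).
#' @param phaseProfiles matrix from \code{\link{buildMarkerProfiles}}.
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param assay exclusions to honor (default none).
#' @return data.frame: gene, phase, and one correlation column per phase
#'   label (\code{cor.G1S}, \code{cor.S}, ...).
#' @export
assignPhase <- function(values, phaseProfiles, design, assay = NULL) {
  prof <- meanProfile(values, design, assay)
  labs <- phaseLevels()
  cors <- t(apply(prof, 1, function(x) {
    z <- .zscore(x)
    vapply(labs, function(ph) {
      ok <- is.finite(z) & is.finite(phaseProfiles[ph, ])
      if (sum(ok) < 3 || all(is.na(z))) return(NA_real_)
      suppressWarnings(cor(z[ok], phaseProfiles[ph, ok]))
    }, numeric(1))
  }))
  phase <- apply(cors, 1, function(r) {
    if (all(is.na(r))) return(NA_character_)
    labs[which.max(replace(r, is.na(r), -Inf))]  # which.max: first = tie order
  })
  out <- data.frame(gene = rownames(prof), phase = unname(phase),
                    row.names = NULL)
  colnames(cors) <- paste0("cor.", gsub("/", "", labs))
  cbind(out, as.data.frame(cors, row.names = NULL))
}

#' Per-phase gene counts and percentages
#'
#' Tabulates assigned phases over the five labels and converts counts to
#' percentages of the assignable total.
#'
#' @param phase character vector of phase labels (or a data.frame from
#'   \code{\link{assignPhase}}), \code{NA} for unassignable genes.
#' @return data.frame: phase, n, percent; plus a \code{total} attribute.
#' @examples
#' # the published per-phase gene counts as input:
#' phaseComposition(rep(phaseLevels(), c(388, 835, 183, 68, 329)))
#' @export
phaseComposition <- function(phase) {
  if (is.data.frame(phase)) phase <- phase$phase
  phase <- phase[!is.na(phase)]
  n <- vapply(phaseLevels(), function(ph) sum(phase == ph), numeric(1))
  out <- data.frame(phase = phaseLevels(), n = unname(n),
                    percent = unname(100 * n / sum(n)), row.names = NULL)
  attr(out, "total") <- sum(n)
  out
}
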