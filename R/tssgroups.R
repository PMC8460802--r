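#' Classify genes by TSS arrangement
#'
#' A gene has a single TSS when its transcripts share one distinct TSS
#' coordinate, and multiple clustered TSSs when it has two or more all
#' within \code{multiSpan} (1 kb). A gene whose TSSs span more than 1 kb
#' (a widely separated variant pair like PCNA's, 6,664 bp apart) is
#' ungrouped. A neighbor is any other gene with a representative TSS
#' within \code{neighborWindow} (10 kb) of this gene's representative TSS.
#' Groups: 1 = single + neighbor, 2 = single + isolated, 3 = multi +
#' neighbor, 4 = multi + isolated.
#'
#' @param catalog a \linkS4class{TssCatalog}.
#' @param neighborWindow neighbor distance in bp (default 10000,
#'   inclusive).
#' @param multiSpan maximum multi-TSS span in bp (default 1000,
#'   inclusive).
#' @param genes optional subset of gene ids to classify (neighbors are
#'   still sought among all genes in the catalog).
#' @return data.frame: gene, group (1:4 or NA for ungrouped), nTss, span,
#'   nearestDist (distance to nearest foreign representative TSS, NA when
#'   none on the same chromosome).
#' @export
classifyTssGroups <- function(catalog, neighborWindow = 10000,
                              multiSpan = 1000, genes = NULL) {
  tab <- as.data.frame(tssTable(catalog))
  nearest <- rep(NA_real_, nrow(tab))
  for (ch in unique(tab$chrom)) {
    i <- which(tab$chrom == ch)
    if (length(i) < 2) next
    o <- i[order(tab$tss[i])]
    pos <- tab$tss[o]
    gaps <- diff(pos)
    nearest[o] <- pmin(c(Inf, gaps), c(gaps, Inf))
  }
  tab$nearestDist <- nearest
  if (!is.null(genes)) tab <- tab[tab$gene_id %in% genes, , drop = FALSE]
  single <- tab$nTss == 1
  multi <- tab$nTss >= 2 & tab$span <= multiSpan
  neighbor <- is.finite(tab$nearestDist) & tab$nearestDist <= neighborWindow
  group <- rep(NA_integer_, nrow(tab))
  group[single & neighbor] <- 1L
  group[single & !neighbor] <- 2L
  group[multi & neighbor] <- 3L
  group[multi & !neighbor] <- 4L
  data.frame(gene = tab$gene_id, group = group, nTss = tab$nTss,
             span = tab$span, nearestDist = tab$nearestDist,
             row.names = NULL)
}

#' Enrichment of highly correlated genes in TSS groups
#'
#' For each TSS group, a 2x2 table of (in group vs rest of background) x
#' (highly correlated vs not) is tested with Fisher's exact test; the
#' odds ratio is the cross-product ratio with Haldane correction at zero
#' cells.
#'
#' @param groupAssign data.frame from \code{\link{classifyTssGroups}}.
#' @param highFlags named logical per gene: highly correlated or not.
#' @param background character vector of background gene ids (e.g. all
#'   cell-cycle genes with ChIP signal).
#' @return data.frame: group, nGroup, nHighGroup, oddsRatio, p. Empty
#'   groups are skipped.
#' @export
fisherEnrichment <- function(groupAssign, highFlags, background) {
  background <- intersect(background, names(highFlags))
  rows <- lapply(sort(unique(groupAssign$group[!is.na(groupAssign$group)])),
                 function(g) {
    inGroup <- intersect(groupAssign$gene[groupAssign$group %in% g],
                         background)
    if (length(inGroup) == 0) return(NULL)
    rest <- setdiff(background, inGroup)
    tab <- matrix(c(sum(highFlags[inGroup]), sum(!highFlags[inGroup]),
                    sum(highFlags[rest]), sum(!highFlags[rest])),
                  2, 2, byrow = TRUE)
    ft <- fisherExact2x2(tab)
    data.frame(group = g, nGroup = length(inGroup),
               nHighGroup = sum(highFlags[inGroup]),
               oddsRatio = ft$oddsRatio, p = ft$p.value)
  })
  do.call(rbind, rows)
}
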