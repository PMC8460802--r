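# Readers/writers for the plain-text interchange formats: TSV matrices
# (genes x samples), FACS fraction tables, GTF annotation (via
# rtracklayer) and BED6 read files. All coordinates on disk follow the
# native convention of the format (BED 0-based half-open, GTF 1-based).

#' Write / read a genes-x-samples TSV matrix
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @return \code{readMatrixTsv} returns the matrix.
#' @export
writeMatrixTsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a FACS fraction table
#'
#' Samples in rows; columns G1, S, G2M.
#'
#' @param facs a \linkS4class{FacsFractions} or a fraction matrix.
#' @param path file path.
#' @return \code{readFacsTsv} returns the fraction matrix.
#' @export
writeFacsTsv <- function(facs, path) {
  m <- if (is(facs, "FacsFractions")) fractions(facs) else facs
  writeMatrixTsv(m, path)
}

#' @rdname writeFacsTsv
#' @export
readFacsTsv <- function(path) {
  m <- readMatrixTsv(path)
  .assert(all(abs(rowSums(m) - 1) < 1e-9), "fraction rows must sum to 1")
  m
}

#' Write / read the annotation as GTF
#'
#' Gene and transcript features with attributes gene_id, transcript_id
#' and gene_biotype, via rtracklayer.
#'
#' @param annotation GRanges as produced by
#'   \code{\link{generateAnnotation}}.
#' @param path file path.
#' @return \code{readGtf} returns the GRanges.
#' @export
writeGtf <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gtf")
}

#' @rdname writeGtf
#' @export
readGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  sort(gr)
}

#' Write / read BED6 read files
#'
#' BED is 0-based half-open with strand in column 6; in memory reads are
#' 1-based GRanges. Malformed lines raise an error naming the line.
#'
#' @param reads GRanges of reads.
#' @param path file path.
#' @return \code{readBedReads} returns a sorted GRanges.
#' @export
writeBedReads <- function(reads, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(reads)),
                   start = GenomicRanges::start(reads) - 1,
                   end = GenomicRanges::end(reads),
                   name = ".", score = 0,
                   strand = as.character(GenomicRanges::strand(reads)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' @rdname writeBedReads
#' @export
readBedReads <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 6)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, call. = FALSE)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  strnd <- vapply(fields, `[[`, "", 6)
  bad <- which(is.na(start) | is.na(end) | end <= start |
               !(strnd %in% c("+", "-", "*")))
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, call. = FALSE)
  sort(GenomicRanges::GRanges(
    vapply(fields, `[[`, "", 1),
    IRanges::IRanges(start = start + 1, end = end), strand = strnd))
}

#' Write / read a chrom.sizes table
#'
#' @param chromSizes named numeric chromosome lengths.
#' @param path file path.
#' @return \code{readChromSizes} returns the named vector.
#' @export
writeChromSizes <- function(chromSizes, path) {
  write.table(data.frame(names(chromSizes), unname(chromSizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' @rdname writeChromSizes
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
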