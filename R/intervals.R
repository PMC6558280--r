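#' Genomic intervals
#'
#' The package represents genomic intervals as plain data frames in the BED
#' convention: 0-based starts, exclusive ends, strand one of \code{"+"},
#' \code{"-"}, \code{"."}. All coordinates are converted at the I/O boundary
#' (e.g. RepeatMasker's 1-based inclusive records), so a single convention
#' holds everywhere inside the package. Interval algorithms (overlap, coverage,
#' merging) are delegated to \pkg{IRanges}/\pkg{GenomicRanges} through the
#' converters below.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy \code{start < end}.
#' @param strand character vector in \code{c("+", "-", ".")}; recycled.
#' @param ... further equal-length columns carried as metadata.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand} plus any extra columns.
#' @export
gintervals <- function(chrom = character(), start = integer(),
                       end = integer(), strand = ".", ...) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_gintervals(df)
  df
}

#' Validate an interval data frame
#'
#' @param x data.frame with at least chrom/start/end (strand optional).
#' @param what label used in error messages.
#' @return \code{x}, invisibly, after checks.
#' @export
validate_gintervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!"strand" %in% names(x)) x$strand <- "."
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop(what, ": NA coordinates")
  if (any(x$start < 0))
    stop(what, ": negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(what, ": start >= end at row ", bad[1])
  if (!all(x$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'")
  invisible(x)
}

#' Sort intervals by (chrom, start, end)
#' @param x interval data.frame.
#' @return sorted data.frame.
#' @export
sort_gintervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Convert intervals to a GRanges (1-based closed)
#' @param x interval data.frame.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a \code{GRanges}.
#' @export
gi_as_granges <- function(x, seqlengths = NULL) {
  if (!"strand" %in% names(x)) x$strand <- "."
  str <- ifelse(x$strand == ".", "*", x$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = str)
  mc <- setdiff(names(x), c("chrom", "start", "end", "strand"))
  if (length(mc))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(x[mc])
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Convert a GRanges back to the package's 0-based interval frame
#' @param gr a \code{GRanges}.
#' @return interval data.frame.
#' @export
granges_as_gi <- function(gr) {
  str <- as.character(BiocGenerics::strand(gr))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = str,
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

# Widths of pairwise overlaps between two interval frames; returns a
# data.frame(query, subject, overlap) of hits with overlap >= min_overlap.
gi_overlaps <- function(query, subject, min_overlap = 1L) {
  qr <- gi_as_granges(query)
  sr <- gi_as_granges(subject)
  hits <- GenomicRanges::findOverlaps(qr, sr, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(qr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(sr)[S4Vectors::subjectHits(hits)]))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits),
             overlap = ov)
}
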