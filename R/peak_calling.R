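#' Per-base read coverage
#'
#' @param reads interval frame of read alignments.
#' @param genome_lengths named integer vector of chromosome lengths.
#' @return an \code{RleList} of per-base counts, one element per chromosome.
#' @export
compute_coverage <- function(reads, genome_lengths) {
  validate_gintervals(reads, "compute_coverage")
  if (nrow(reads)) {
    bad <- !(reads$chrom %in% names(genome_lengths)) |
      reads$end > genome_lengths[reads$chrom] | reads$start < 0
    if (any(bad))
      stop("read outside genome bounds at row ", which(bad)[1])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(reads$chrom, levels = names(genome_lengths)),
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    seqlengths = genome_lengths)
  GenomicRanges::coverage(gr)
}

#' Deterministic threshold/merge/width peak caller
#'
#' Maximal runs of coverage at or above \code{min_height} are taken as
#' candidate peaks; runs separated by fewer than \code{merge_gap} uncovered
#' bases are merged; merged runs shorter than \code{min_width} are discarded.
#' Peaks are unstranded (strand is assigned later from the repeat
#' annotation).
#'
#' @param coverage an \code{RleList} from \code{\link{compute_coverage}}.
#' @param min_height minimum per-base count (>= 1).
#' @param merge_gap merge runs separated by fewer than this many bases.
#' @param min_width discard merged runs shorter than this.
#' @return sorted interval frame of peaks.
#' @export
call_peaks <- function(coverage, min_height = 5, merge_gap = 100,
                       min_width = 50) {
  if (min_height < 1 || merge_gap < 0 || min_width < 1)
    stop("invalid peak-calling parameters")
  out <- list()
  for (chrom in names(coverage)) {
    runs <- IRanges::slice(coverage[[chrom]], lower = min_height,
                           rangesOnly = TRUE)
    if (!length(runs)) next
    if (merge_gap > 0)
      runs <- IRanges::reduce(runs, min.gapwidth = merge_gap)
    runs <- runs[IRanges::width(runs) >= min_width]
    if (!length(runs)) next
    out[[chrom]] <- data.frame(chrom = chrom,
                               start = BiocGenerics::start(runs) - 1L,
                               end = BiocGenerics::end(runs),
                               strand = ".", stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else gintervals()
  rownames(res) <- NULL
  sort_gintervals(res)
}

#' Replicate-consensus peaks
#'
#' Consensus is defined per base: genomic bases covered by peaks in at least
#' \code{min_replicates} replicates are extracted as maximal runs. Each
#' output peak carries \code{support}, the maximum per-base replicate count
#' within it. This mirrors the filtering of RACE-Seq loci to those present in
#' at least two of three replicates.
#'
#' @param peaksets list of peak interval frames, one per replicate.
#' @param min_replicates minimum replicate depth (default 2).
#' @return interval frame with a \code{support} column.
#' @export
replicate_consensus <- function(peaksets, min_replicates = 2) {
  if (min_replicates > length(peaksets))
    stop("min_replicates exceeds the number of replicate peak sets")
  chroms <- unique(unlist(lapply(peaksets, function(p) p$chrom)))
  if (!length(chroms)) {
    out <- gintervals()
    out$support <- integer()
    return(out)
  }
  all <- do.call(rbind, lapply(peaksets, function(p)
    p[, c("chrom", "start", "end")]))
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end))
  depth <- GenomicRanges::coverage(gr)
  out <- list()
  for (chrom in names(depth)) {
    runs <- IRanges::slice(depth[[chrom]], lower = min_replicates,
                           rangesOnly = TRUE)
    if (!length(runs)) next
    supp <- vapply(seq_along(runs), function(i)
      as.integer(max(S4Vectors::window(depth[[chrom]],
                                       BiocGenerics::start(runs)[i],
                                       BiocGenerics::end(runs)[i]))),
      integer(1))
    out[[chrom]] <- data.frame(chrom = chrom,
                               start = BiocGenerics::start(runs) - 1L,
                               end = BiocGenerics::end(runs),
                               strand = ".", support = supp,
                               stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    r <- gintervals(); r$support <- integer(); r
  }
  rownames(res) <- NULL
  sort_gintervals(res)
}

#' Union-merge of peak sets
#'
#' Union of intervals with overlapping or book-ended intervals coalesced;
#' used to pool consensus peaks across the samples of a group before
#' cross-group comparison.
#'
#' @param peaksets list of peak interval frames.
#' @return merged, sorted interval frame.
#' @export
merge_peaksets <- function(peaksets) {
  all <- do.call(rbind, lapply(peaksets, function(p)
    p[, c("chrom", "start", "end")]))
  if (is.null(all) || !nrow(all)) return(gintervals())
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end))
  m <- GenomicRanges::reduce(gr)
  res <- data.frame(chrom = as.character(GenomicRanges::seqnames(m)),
                    start = BiocGenerics::start(m) - 1L,
                    end = BiocGenerics::end(m),
                    strand = ".", stringsAsFactors = FALSE)
  sort_gintervals(res)
}

#' Fraction of a sample's peaks present in all replicates
#'
#' Pools the replicate peak sets, merges them into per-sample regions, and
#' reports the fraction of merged regions overlapped by a peak in every
#' replicate. On real RACE-Seq data this sharing fraction was low (7-30%),
#' which motivated the 2-of-3 consensus filter.
#'
#' @param peaksets list of per-replicate peak interval frames for one sample.
#' @return fraction in [0, 1] (NA when no peaks at all).
#' @export
replicate_sharing <- function(peaksets) {
  merged <- merge_peaksets(peaksets)
  if (!nrow(merged)) return(NA_real_)
  hit <- vapply(peaksets, function(p) {
    if (!nrow(p)) return(rep(FALSE, nrow(merged)))
    ov <- gi_overlaps(merged, p)
    seq_len(nrow(merged)) %in% ov$query
  }, logical(nrow(merged)))
  hit <- matrix(hit, nrow = nrow(merged))
  mean(rowSums(hit) == length(peaksets))
}
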