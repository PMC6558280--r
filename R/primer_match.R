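#' Hamming distance between a primer and an equal-length window
#'
#' A position where either sequence carries \code{N} counts as a mismatch
#' (an undetermined base cannot be assumed to anneal).
#'
#' @param primer,window uppercase DNA strings of equal length (A/C/G/T/N).
#' @return integer mismatch count.
#' @export
count_mismatches <- function(primer, window) {
  if (nchar(primer) != nchar(window))
    stop("primer and window must have equal length")
  p <- strsplit(primer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  sum(p != w | p == "N" | w == "N")
}

#' Scan one repeat instance for the best ungapped primer match
#'
#' The instance sequence is given in genomic orientation; for a
#' \code{"-"}-strand instance it is reverse-complemented first so the scan
#' runs 5' to 3' along the transcribed strand. The minimal Hamming distance
#' over all ungapped offsets is returned, with the leftmost offset on ties.
#'
#' @param primer uppercase DNA string.
#' @param instance_sequence uppercase DNA string, genomic orientation.
#' @param strand \code{"+"} or \code{"-"} (\code{"."} treated as \code{"+"}).
#' @return list with \code{best_offset} (0-based, from the instance 5' end on
#'   the transcribed strand), \code{mismatches}.
#' @export
scan_instance <- function(primer, instance_sequence, strand = "+") {
  if (nchar(instance_sequence) < nchar(primer))
    stop("instance shorter than primer")
  seq <- if (identical(strand, "-")) revcomp(instance_sequence)
         else instance_sequence
  p <- utf8ToInt(primer)
  s <- utf8ToInt(seq)
  nN <- utf8ToInt("N")
  np <- length(p); L <- length(s)
  offs <- 0:(L - np)
  idx <- outer(offs, seq_len(np), `+`)          # L-np+1 x np index matrix
  wins <- matrix(s[idx], nrow = length(offs))
  pm <- matrix(p, nrow = length(offs), ncol = np, byrow = TRUE)
  mm <- rowSums(wins != pm | wins == nN | pm == nN)
  best <- which.min(mm)                          # which.min takes the leftmost
  list(best_offset = offs[best], mismatches = as.integer(mm[best]))
}

#' Primer compatibility of every repeat instance
#'
#' Extracts each instance's sequence from the genome, scans it with
#' \code{\link{scan_instance}}, and flags instances whose best match is within
#' the mismatch budget as amplifiable. The mismatch histogram summarises how
#' far the family copies have diverged from the primer region.
#'
#' @param primer uppercase DNA string.
#' @param repeats repeat interval data.frame (\code{instance_id},
#'   \code{family}).
#' @param genome named character vector of chromosome sequences.
#' @param max_mismatches mismatch budget (default 8).
#' @return data.frame (instance_id, family, best_offset, mismatches,
#'   amplifiable) with attribute \code{"histogram"} (table of mismatch
#'   counts).
#' @export
amplifiable_set <- function(primer, repeats, genome, max_mismatches = 8) {
  validate_gintervals(repeats, "amplifiable_set")
  n <- nrow(repeats)
  res <- data.frame(instance_id = repeats$instance_id,
                    family = repeats$family,
                    best_offset = integer(n),
                    mismatches = integer(n),
                    amplifiable = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    chrom <- repeats$chrom[i]
    if (!chrom %in% names(genome))
      stop("instance ", repeats$instance_id[i], " on unknown chromosome")
    if (repeats$end[i] > nchar(genome[[chrom]]))
      stop("instance ", repeats$instance_id[i], " outside genome bounds")
    seq <- substr(genome[[chrom]], repeats$start[i] + 1L, repeats$end[i])
    hit <- scan_instance(primer, seq, repeats$strand[i])
    res$best_offset[i] <- hit$best_offset
    res$mismatches[i] <- hit$mismatches
  }
  res$amplifiable <- res$mismatches <= max_mismatches
  attr(res, "histogram") <- table(mismatches = res$mismatches)
  res
}

#' Reverse complement of a DNA string (A/C/G/T/N)
#' @param x DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
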