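#' Annotate peaks with repeat instances and families
#'
#' Each peak is assigned to the repeat instance with maximal overlap of at
#' least \code{min_overlap_bases}; ties go to the repeat with the smaller
#' start. Unassigned peaks are labelled \code{"non-repeat"}. The peak
#' inherits the repeat's strand (RACE peaks are unstranded until then).
#'
#' @param peaks interval frame of (consensus) peaks.
#' @param repeats repeat interval frame (\code{instance_id}, \code{family}).
#' @param min_overlap_bases minimum overlap (default 1).
#' @return data.frame of annotated loci (locus_id, peak coordinates,
#'   instance_id, family, assigned_strand) with attribute
#'   \code{"family_table"} (counts and fractions per family over
#'   repeat-assigned loci).
#' @export
annotate_peaks_to_repeats <- function(peaks, repeats, min_overlap_bases = 1) {
  if (min_overlap_bases < 1) stop("min_overlap_bases must be >= 1")
  validate_gintervals(peaks, "peaks")
  n <- nrow(peaks)
  res <- data.frame(locus_id = sprintf("locus_%04d", seq_len(n)),
                    chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end,
                    instance_id = NA_character_,
                    family = "non-repeat",
                    assigned_strand = ".",
                    stringsAsFactors = FALSE)
  if (n && nrow(repeats)) {
    ov <- gi_overlaps(peaks, repeats, min_overlap = min_overlap_bases)
    if (nrow(ov)) {
      # max overlap, ties to smaller repeat start
      ov <- ov[order(ov$query, -ov$overlap, repeats$start[ov$subject]), ]
      ov <- ov[!duplicated(ov$query), ]
      res$instance_id[ov$query] <- repeats$instance_id[ov$subject]
      res$family[ov$query] <- repeats$family[ov$subject]
      res$assigned_strand[ov$query] <- repeats$strand[ov$subject]
    }
  }
  assigned <- res$family[res$family != "non-repeat"]
  tab <- table(family = assigned)
  attr(res, "family_table") <- data.frame(
    family = names(tab), count = as.integer(tab),
    fraction = if (length(assigned)) as.integer(tab) / length(assigned)
               else numeric(length(tab)),
    stringsAsFactors = FALSE)
  res
}

#' Family detection bias against the genomic background
#'
#' Compares the family composition of detected loci with the genomic repeat
#' complement, the comparison behind the observation that over half of the
#' LTRs detected in tumour cells are THE1B despite a balanced genomic
#' representation.
#'
#' @param family_counts named counts (or the \code{"family_table"} attribute)
#'   of detected loci per family.
#' @param genome_family_counts named counts of repeat instances per family in
#'   the annotation.
#' @return data.frame (family, detected_fraction, genome_fraction, ratio),
#'   fractions summing to 1 in each column.
#' @export
family_bias <- function(family_counts, genome_family_counts) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$count, x$family)
    else stats::setNames(as.integer(x), names(x))
  }
  det <- as_named(family_counts)
  bg <- as_named(genome_family_counts)
  if (!length(det) || sum(det) == 0)
    stop("empty detected family table")
  fams <- union(names(bg), names(det))
  d <- stats::setNames(rep(0, length(fams)), fams); d[names(det)] <- det
  b <- stats::setNames(rep(0, length(fams)), fams); b[names(bg)] <- bg
  df <- data.frame(family = fams,
                   detected_fraction = unname(d) / sum(d),
                   genome_fraction = unname(b) / sum(b),
                   stringsAsFactors = FALSE)
  df$ratio <- df$detected_fraction / df$genome_fraction
  rownames(df) <- NULL
  df
}

# Strand-aware promoter windows as an interval frame: 'up' bases upstream of
# the TSS to 'down' bases downstream, along the gene's transcription
# direction. Half-open genomic coordinates.
promoter_windows <- function(genes, promoter_upstream = 1000,
                             promoter_downstream = 100) {
  up <- promoter_upstream; down <- promoter_downstream
  start <- ifelse(genes$strand == "+", genes$tss - up,
                  genes$tss - down + 1L)
  end <- ifelse(genes$strand == "+", genes$tss + down,
                genes$tss + up + 1L)
  data.frame(chrom = genes$chrom, start = pmax(start, 0L), end = end,
             strand = genes$strand, gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

#' Classify loci by genomic region
#'
#' Labels each locus \code{TSS_promoter} if it overlaps any gene's
#' strand-aware promoter window (default 1 kb upstream to +100 bp downstream
#' of the TSS), else \code{intragenic} if it overlaps any gene body, else
#' \code{intergenic}. Precedence: promoter > intragenic > intergenic, so the
#' labels partition the loci.
#'
#' @param loci interval frame (e.g. from
#'   \code{\link{annotate_peaks_to_repeats}}).
#' @param genes gene interval frame with \code{tss}.
#' @param promoter_upstream,promoter_downstream promoter window extents in
#'   bases.
#' @return character vector of region labels, one per locus.
#' @export
annotate_genomic_region <- function(loci, genes, promoter_upstream = 1000,
                                    promoter_downstream = 100) {
  n <- nrow(loci)
  region <- rep("intergenic", n)
  if (!n) return(character())
  if (nrow(genes)) {
    body_ov <- gi_overlaps(loci, genes)
    region[unique(body_ov$query)] <- "intragenic"
    prom <- promoter_windows(genes, promoter_upstream, promoter_downstream)
    prom_ov <- gi_overlaps(loci, prom)
    region[unique(prom_ov$query)] <- "TSS_promoter"
  }
  region
}
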