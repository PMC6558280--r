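#' FPKM from raw counts
#'
#' \eqn{FPKM = count \cdot 10^9 / (length \cdot library\_size)}.
#'
#' @param counts non-negative gene x sample count matrix.
#' @param gene_lengths positive lengths in bases, one per gene.
#' @param library_sizes positive totals, one per sample.
#' @return FPKM matrix with the same dimnames.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts / gene_lengths, 2, library_sizes, `/`) * 1e9
}

#' Per-gene log2 fold change with a pseudocount
#'
#' \eqn{\log_2((a + c) / (b + c))}, default \eqn{c = 1}; symmetric and safe
#' at zero expression.
#'
#' @param a,b named numeric vectors over the same gene universe (e.g.
#'   replicate-averaged FPKM of two conditions).
#' @param pseudocount positive stabiliser.
#' @return named numeric vector of log2 fold changes.
#' @export
fold_change <- function(a, b, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (is.null(names(a)) || is.null(names(b)) ||
      !identical(sort(names(a)), sort(names(b))))
    stop("gene universes of the two samples differ")
  b <- b[names(a)]
  log2((a + pseudocount) / (b + pseudocount))
}

#' Nearest same-strand downstream gene of a stranded locus
#'
#' Implements the upstream-LTR selection rule for metagene profiling: among
#' genes on the locus strand whose TSS lies downstream of the locus 3' end
#' in transcription orientation, the nearest is returned; a locus overlapping
#' any promoter window (it is then a TSS-type locus) yields no link.
#' Distance is measured from the locus 3' end to the TSS.
#'
#' @param loci stranded interval frame (strand \code{"+"}/\code{"-"}; a
#'   \code{"."} strand is an error - strand must be inferred from the repeat
#'   annotation first).
#' @param genes gene interval frame with \code{tss} and \code{gene_id}.
#' @param promoter_upstream,promoter_downstream promoter window extents.
#' @param max_distance optional cap on the link distance (NULL = none).
#' @return data.frame (locus index per row): \code{gene_id} (NA when no
#'   link), \code{distance}.
#' @export
nearest_downstream_gene <- function(loci, genes, promoter_upstream = 1000,
                                    promoter_downstream = 100,
                                    max_distance = NULL) {
  if (any(loci$strand == "."))
    stop("locus strand must be inferred before downstream-gene linking")
  n <- nrow(loci)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!n || !nrow(genes)) return(out)
  prom <- promoter_windows(genes, promoter_upstream, promoter_downstream)
  in_prom <- unique(gi_overlaps(loci, prom)$query)
  for (i in seq_len(n)) {
    if (i %in% in_prom) next
    same <- genes[genes$strand == loci$strand[i] &
                    genes$chrom == loci$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    if (loci$strand[i] == "+") {
      d <- same$tss - loci$end[i]
    } else {
      d <- loci$start[i] - same$tss - 1L
    }
    ok <- d >= 0
    if (!is.null(max_distance)) ok <- ok & d <= max_distance
    if (!any(ok)) next
    j <- which(ok)[which.min(d[ok])]
    out$gene_id[i] <- same$gene_id[j]
    out$distance[i] <- d[j]
  }
  out
}

# Mean per-base signal in fixed-width bins of a numeric vector.
.bin_means <- function(v, binsize) {
  nb <- length(v) / binsize
  colMeans(matrix(v, nrow = binsize, ncol = nb))
}

#' Strand-oriented metagene profile around loci
#'
#' Extracts \code{window} bases centred on each locus midpoint from the plus
#' and minus signal tracks; for \code{"-"} loci the extract is reversed and
#' the tracks swapped, so "sense" always means the locus's own transcription
#' orientation. Per-bin means are averaged across loci. Loci whose window
#' leaves the chromosome are skipped and counted.
#'
#' @param loci stranded interval frame.
#' @param signal_plus,signal_minus \code{RleList} coverage tracks.
#' @param window total window width in bases (even multiple of
#'   \code{binsize}).
#' @param binsize bin width in bases.
#' @return list: \code{n_loci} (used), \code{n_skipped}, \code{offsets}
#'   (bin-start offsets from the locus midpoint), \code{sense_mean},
#'   \code{antisense_mean}.
#' @export
meta_profile <- function(loci, signal_plus, signal_minus, window = 10000,
                         binsize = 50) {
  if (window %% (2 * binsize) != 0)
    stop("window must be an even multiple of binsize")
  half <- window / 2
  nb <- window / binsize
  sense <- anti <- numeric(nb)
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]
    mid <- floor((loci$start[i] + loci$end[i]) / 2)
    a <- mid - half; b <- mid + half          # [a, b) half-open
    L <- length(signal_plus[[chrom]])
    if (a < 0 || b > L) { skipped <- skipped + 1L; next }
    vp <- as.numeric(S4Vectors::window(signal_plus[[chrom]], a + 1L, b))
    vm <- as.numeric(S4Vectors::window(signal_minus[[chrom]], a + 1L, b))
    if (loci$strand[i] == "-") {
      s <- rev(vm); t <- rev(vp)
    } else {
      s <- vp; t <- vm
    }
    sense <- sense + .bin_means(s, binsize)
    anti <- anti + .bin_means(t, binsize)
    used <- used + 1L
  }
  if (used > 0) { sense <- sense / used; anti <- anti / used }
  list(n_loci = used, n_skipped = skipped,
       offsets = seq(-half, half - binsize, by = binsize),
       sense_mean = sense, antisense_mean = anti)
}

# Fraction of bases >= min_signal on the given strand track between two
# genomic positions (half-open).
.signal_fraction <- function(track, chrom, from, to, min_signal) {
  if (to <= from) return(1)
  v <- as.numeric(S4Vectors::window(track[[chrom]], from + 1L, to))
  mean(v >= min_signal)
}

#' Four-way classification of LTR-initiated transcripts
#'
#' Assigns each stranded locus exactly one label:
#' \describe{
#'   \item{intragenic_isoform}{locus inside a same-strand gene body (the LTR
#'     promoter produces a shorter isoform).}
#'   \item{antisense}{locus strand opposes the overlapping gene, or the
#'     nearest downstream gene reached by contiguous sense signal.}
#'   \item{upstream_promoter}{intergenic locus with a same-strand downstream
#'     gene within \code{max_link_distance} and contiguous sense signal
#'     reaching it.}
#'   \item{intergenic_lncRNA}{intergenic locus with sense signal but no
#'     qualifying gene link (a previously unannotated lncRNA).}
#' }
#' "Contiguous sense signal" means per-base coverage of at least
#' \code{min_signal} over at least \code{min_signal_fraction} of the bases
#' between the locus 3' end and the gene.
#'
#' @param loci stranded interval frame.
#' @param genes gene interval frame.
#' @param signal_plus,signal_minus \code{RleList} coverage tracks (pooled
#'   over the samples in which each locus is active is the pipeline default).
#' @param max_link_distance cap on downstream gene linking in bases.
#' @param min_signal per-base signal threshold.
#' @param min_signal_fraction required covered fraction between locus and
#'   gene.
#' @return character vector of labels, one per locus.
#' @export
classify_ltr_transcript <- function(loci, genes, signal_plus, signal_minus,
                                    max_link_distance = 50000,
                                    min_signal = 1,
                                    min_signal_fraction = 0.8) {
  ltr_gene_links(loci, genes, signal_plus, signal_minus, max_link_distance,
                 min_signal, min_signal_fraction)$relation
}

#' LTR-to-gene links with transcript relations
#'
#' The classification of \code{\link{classify_ltr_transcript}} together with
#' the gene each LTR-initiated transcript involves: the shorter-isoform host
#' gene (\code{intragenic_isoform}, distance 0), the downstream promoter
#' target (\code{upstream_promoter}, distance from the locus 3' end to the
#' gene), the gene read into antisense (\code{antisense}), or none
#' (\code{intergenic_lncRNA}).
#'
#' @inheritParams classify_ltr_transcript
#' @return data.frame with one row per locus: \code{relation},
#'   \code{gene_id} (NA for lncRNA loci), \code{distance}.
#' @export
ltr_gene_links <- function(loci, genes, signal_plus, signal_minus,
                           max_link_distance = 50000,
                           min_signal = 1,
                           min_signal_fraction = 0.8) {
  if (any(loci$strand == "."))
    stop("loci must be stranded for transcript classification")
  n <- nrow(loci)
  out <- data.frame(relation = rep("intergenic_lncRNA", n),
                    gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  ov <- gi_overlaps(loci, genes)
  for (i in seq_len(n)) {
    track <- if (loci$strand[i] == "+") signal_plus else signal_minus
    hit <- ov$subject[ov$query == i]
    if (length(hit)) {
      same <- genes$strand[hit] == loci$strand[i]
      j <- if (any(same)) hit[same][1] else hit[1]
      out$relation[i] <- if (any(same)) "intragenic_isoform" else "antisense"
      out$gene_id[i] <- genes$gene_id[j]
      out$distance[i] <- 0
      next
    }
    # intergenic: nearest downstream gene edge reached by sense signal?
    g <- genes[genes$chrom == loci$chrom[i], , drop = FALSE]
    if (loci$strand[i] == "+") {
      dd <- g$start - loci$end[i]
    } else {
      dd <- loci$start[i] - g$end
    }
    ok <- dd >= 0 & dd <= max_link_distance
    if (any(ok)) {
      j <- which(ok)[which.min(dd[ok])]
      reach <- if (loci$strand[i] == "+")
        .signal_fraction(track, loci$chrom[i], loci$end[i], g$start[j],
                         min_signal)
      else
        .signal_fraction(track, loci$chrom[i], g$end[j], loci$start[i],
                         min_signal)
      if (reach >= min_signal_fraction) {
        out$relation[i] <- if (g$strand[j] == loci$strand[i])
          "upstream_promoter" else "antisense"
        out$gene_id[i] <- g$gene_id[j]
        out$distance[i] <- dd[j]
      }
    }
  }
  out
}

#' Enrichment of upregulated genes among LTR-linked genes
#'
#' Hypergeometric upper tail with population N = all genes, successes K =
#' genes with log2 fold change at or above \code{up_threshold}, draws n =
#' genes linked to active LTRs, observed k = linked genes that are
#' upregulated.
#'
#' @param linked_genes character vector of gene ids linked to active LTRs.
#' @param fold_changes named log2 fold-change vector over all genes.
#' @param up_threshold log2 fold-change cutoff for "upregulated" (default 1).
#' @return list (population_N, successes_K, draws_n, observed_k, p_value).
#' @export
ltr_fc_enrichment <- function(linked_genes, fold_changes, up_threshold = 1) {
  linked <- unique(linked_genes[!is.na(linked_genes)])
  if (!length(linked)) stop("empty link set")
  if (!all(linked %in% names(fold_changes)))
    stop("linked genes missing from fold-change table")
  N <- length(fold_changes)
  up <- names(fold_changes)[fold_changes >= up_threshold]
  K <- length(up)
  n <- length(linked)
  k <- length(intersect(linked, up))
  list(population_N = N, successes_K = K, draws_n = n, observed_k = k,
       p_value = hypergeometric_tail(N, K, n, k))
}

#' Sample correlation clustering over LTR-linked genes
#'
#' Pearson correlation between sample columns of log2(FPKM + 1) restricted
#' to the linked genes, followed by average-linkage clustering on
#' \eqn{1 - r}.
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param linked_genes gene ids to restrict to (>= 3 required).
#' @return list with \code{correlation} (sample matrix) and \code{hclust}.
#' @export
correlation_cluster <- function(fpkm, linked_genes) {
  genes <- intersect(rownames(fpkm), unique(linked_genes))
  if (length(genes) < 3) stop("need at least 3 linked genes")
  if (ncol(fpkm) < 2) stop("need at least 2 samples")
  x <- log2(fpkm[genes, , drop = FALSE] + 1)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample column: ", colnames(x)[sds == 0][1])
  r <- stats::cor(x)
  list(correlation = r,
       hclust = stats::hclust(stats::as.dist(1 - r), method = "average"))
}
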