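#' Build a binary activation matrix from per-sample consensus loci
#'
#' The locus universe is the union of repeat instances hit by any sample's
#' consensus peaks; an entry is 1 iff that sample's consensus peaks overlap
#' the instance.
#'
#' @param consensus_by_sample named list (sample -> annotated locus frame
#'   from \code{\link{annotate_peaks_to_repeats}}, or any frame with an
#'   \code{instance_id} column).
#' @param repeats repeat interval frame; fixes instance ordering.
#' @return binary integer matrix, rows = instance ids, columns = samples.
#' @export
build_activation_matrix <- function(consensus_by_sample, repeats) {
  hit_ids <- lapply(consensus_by_sample, function(x) {
    ids <- x$instance_id
    unique(ids[!is.na(ids)])
  })
  universe <- repeats$instance_id[repeats$instance_id %in%
                                    unique(unlist(hit_ids))]
  mat <- matrix(0L, nrow = length(universe), ncol = length(hit_ids),
                dimnames = list(universe, names(consensus_by_sample)))
  for (s in names(hit_ids)) mat[hit_ids[[s]], s] <- 1L
  mat
}

#' Group-specific and shared active-locus sets
#'
#' Uses merged-peak semantics: a locus counts for a group when it is active
#' in at least one of the group's samples. "Shared within" a group means
#' active in all of that group's samples; "unique to" a group additionally
#' excludes any activity in the other group. This is the set arithmetic
#' behind tumour-specific versus control-specific active LTR counts.
#'
#' @param activation binary activation matrix.
#' @param groupA,groupB disjoint character vectors of sample ids.
#' @return list of locus-id vectors: \code{a_specific}, \code{b_specific},
#'   \code{shared}, \code{shared_within_a}, \code{shared_within_b},
#'   \code{unique_to_a}, \code{unique_to_b}, plus \code{counts}.
#' @export
group_specific_sets <- function(activation, groupA, groupB) {
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  if (!length(groupA) || !length(groupB))
    stop("groups must be non-empty")
  loci <- rownames(activation)
  inA <- rowSums(activation[, groupA, drop = FALSE]) > 0
  inB <- rowSums(activation[, groupB, drop = FALSE]) > 0
  allA <- rowSums(activation[, groupA, drop = FALSE]) == length(groupA)
  allB <- rowSums(activation[, groupB, drop = FALSE]) == length(groupB)
  res <- list(a_specific = loci[inA & !inB],
              b_specific = loci[inB & !inA],
              shared = loci[inA & inB],
              shared_within_a = loci[allA],
              shared_within_b = loci[allB],
              unique_to_a = loci[allA & !inB],
              unique_to_b = loci[allB & !inA])
  res$counts <- vapply(res, length, integer(1))
  res
}

#' Dice similarity of two locus sets
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}; 1 iff the non-empty sets are equal, 0
#' for disjoint sets.
#'
#' @param setA,setB vectors of locus ids (not both empty).
#' @return numeric score in [0, 1].
#' @export
dice_index <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  if (!length(a) && !length(b))
    stop("Dice index undefined for two empty sets")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Dice similarity matrix over samples
#'
#' @param activation binary activation matrix (loci x samples).
#' @return symmetric numeric matrix of Dice scores; diagonal 1 for samples
#'   with at least one active locus.
#' @export
dice_matrix <- function(activation) {
  samples <- colnames(activation)
  sets <- lapply(samples, function(s)
    rownames(activation)[activation[, s] == 1L])
  names(sets) <- samples
  n <- length(samples)
  m <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n)) for (j in i:n) {
    m[i, j] <- m[j, i] <- dice_index(sets[[i]], sets[[j]])
  }
  m
}

#' Agglomerative clustering of a similarity matrix
#'
#' Average-linkage clustering on distance \eqn{1 - s}. Deterministic: ties
#' are resolved by \code{\link[stats]{hclust}}'s order-dependent rule, so a
#' fixed sample order gives a fixed tree.
#'
#' @param similarity square symmetric similarity matrix in [0, 1].
#' @return an \code{\link[stats]{hclust}} object.
#' @export
cluster_similarity <- function(similarity) {
  if (nrow(similarity) < 2) stop("need at least 2 samples to cluster")
  if (max(abs(similarity - t(similarity))) > 1e-12)
    stop("similarity matrix must be symmetric")
  stats::hclust(stats::as.dist(1 - similarity), method = "average")
}

#' Export a dendrogram as a Newick string
#' @param hc an \code{hclust} object.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Do two groups form separate clades?
#'
#' Cuts the tree into two clusters and checks the cut reproduces the given
#' partition (used to ask whether tumour-like samples cluster away from
#' controls).
#'
#' @param hc an \code{hclust} object.
#' @param groupA,groupB sample id vectors partitioning the leaves.
#' @return logical.
#' @export
clades_separate_groups <- function(hc, groupA, groupB) {
  k2 <- stats::cutree(hc, k = 2)
  a <- k2[groupA]; b <- k2[groupB]
  length(unique(a)) == 1 && length(unique(b)) == 1 && a[1] != b[1]
}

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\code{N} population,
#' \code{K} successes, \code{n} draws), accumulated in log space for
#' numerical stability. Used for enrichment of active LTRs near upregulated
#' genes and for overlap significance between sample sets.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @param k observed successes among the draws.
#' @return p-value in (0, 1].
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(n, K))
    stop("impossible hypergeometric parameters")
  if (k == 0) return(1)
  i <- k:min(n, K)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  p <- exp(m) * sum(exp(lt - m))
  min(p, 1)
}

#' Benjamini-Hochberg adjustment helper
#' @param p numeric vector of p-values.
#' @return adjusted p-values (thin wrapper over \code{\link[stats]{p.adjust}}).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
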