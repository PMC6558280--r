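#' Recovery of planted activation by the peak-calling chain
#'
#' Compares, per sample, the repeat instances present in the consensus
#' annotation with the generator's capture ground truth: a locus is
#' detectable in a sample when it emitted reads in at least
#' \code{min_replicates} replicates (activation and amplifiability alone do
#' not guarantee detectability because replicate capture dropout may erase a
#' locus from the data).
#'
#' @param captured locus x sample x replicate logical array from
#'   \code{\link{simulate_race_reads}}.
#' @param annotated_by_sample named list of annotated locus frames (one per
#'   sample, from \code{\link{annotate_peaks_to_repeats}} on consensus
#'   peaks).
#' @param min_replicates replicate depth defining detectability (default 2).
#' @return list: \code{recovery}, \code{fdr}, \code{n_detectable},
#'   \code{n_detected}.
#' @export
recovery_stats <- function(captured, annotated_by_sample,
                           min_replicates = 2) {
  tp <- 0L; fp <- 0L; n_truth <- 0L; n_det <- 0L
  for (s in names(annotated_by_sample)) {
    truth <- dimnames(captured)[[1]][
      rowSums(captured[, s, , drop = FALSE], dims = 1) >= min_replicates]
    ann <- annotated_by_sample[[s]]
    det <- unique(ann$instance_id[!is.na(ann$instance_id)])
    n_nonrep <- sum(ann$family == "non-repeat")
    tp <- tp + length(intersect(det, truth))
    fp <- fp + length(setdiff(det, truth)) + n_nonrep
    n_truth <- n_truth + length(truth)
    n_det <- n_det + length(det) + n_nonrep
  }
  list(recovery = if (n_truth) tp / n_truth else NA_real_,
       fdr = if (n_det) fp / n_det else NA_real_,
       n_detectable = n_truth, n_detected = n_det)
}

# Element-wise sum of a list of RleList coverage tracks.
.pool_tracks <- function(tracks) Reduce(`+`, tracks)

#' Run the full analysis chain on one simulated dataset
#'
#' simulate -> primer scan -> per-replicate peak calling -> replicate
#' consensus -> repeat/region annotation -> activation matrix, group sets,
#' Dice clustering, overlap tests -> expression integration (links,
#' fold changes, enrichment, metagene profile, transcript typology,
#' correlation clustering). Deterministic under \code{seed}. When
#' \code{outdir} is given every stage output is written in a fixed layout
#' together with an md5 checksum manifest.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed root seed for every stage (defaults to \code{config$seed}).
#' @param outdir optional output directory.
#' @param peak_params list(min_height, merge_gap, min_width).
#' @param min_replicates consensus replicate depth.
#' @param promoter_upstream,promoter_downstream promoter window extents.
#' @param max_link_distance downstream-gene linking cap in bases.
#' @param up_threshold log2 fold-change cutoff for upregulation.
#' @return a list with all stage results (see the methods vignette for the
#'   full inventory).
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         outdir = NULL,
                         peak_params = list(min_height = 5, merge_gap = 100,
                                            min_width = 50),
                         min_replicates = 2,
                         promoter_upstream = 1000,
                         promoter_downstream = 100,
                         max_link_distance = 50000,
                         up_threshold = 1) {
  config$seed <- seed
  sim <- simulate_dataset(config, seed)
  glen <- genome_lengths(sim$genome)
  samples <- unlist(config$samples, use.names = FALSE)
  tumour <- config$samples$tumour
  control <- config$samples$control

  # peak calling per replicate, consensus per sample
  peaks <- list(); consensus <- list(); sharing <- numeric(0)
  for (s in samples) {
    reps <- lapply(sim$race$reads[[s]], function(rd) {
      cov <- compute_coverage(rd, glen)
      call_peaks(cov, peak_params$min_height, peak_params$merge_gap,
                 peak_params$min_width)
    })
    peaks[[s]] <- reps
    consensus[[s]] <- replicate_consensus(reps, min_replicates)
    sharing[s] <- replicate_sharing(reps)
  }

  # annotation of consensus peaks
  annotated <- lapply(consensus, function(p)
    annotate_peaks_to_repeats(p, sim$repeats))
  # locus geometry for region/typology: the assigned instance where present
  inst_row <- stats::setNames(seq_len(nrow(sim$repeats)),
                              sim$repeats$instance_id)
  locus_frame <- function(ann) {
    idx <- inst_row[ann$instance_id]
    out <- data.frame(chrom = ann$chrom, start = ann$start, end = ann$end,
                      strand = ann$assigned_strand,
                      instance_id = ann$instance_id,
                      stringsAsFactors = FALSE)
    has <- !is.na(idx)
    out[has, c("chrom", "start", "end", "strand")] <-
      sim$repeats[idx[has], c("chrom", "start", "end", "strand")]
    out
  }
  regions <- lapply(annotated, function(ann) {
    lf <- locus_frame(ann)
    annotate_genomic_region(lf, sim$genes, promoter_upstream,
                            promoter_downstream)
  })

  # cross-sample comparisons
  act <- build_activation_matrix(annotated, sim$repeats)
  sets <- group_specific_sets(act, tumour, control)
  dmat <- dice_matrix(act)
  hc <- cluster_similarity(dmat)
  # overlap significance between tumour repertoires; the population is the
  # pool a sample's active set is drawn from - every amplifiable instance -
  # not the detected union (which conditions on the outcome)
  n_pool <- sum(sim$race$scan$amplifiable)
  pair_tests <- list()
  if (length(tumour) >= 2) {
    for (i in seq_len(length(tumour) - 1)) for (j in (i + 1):length(tumour)) {
      A <- rownames(act)[act[, tumour[i]] == 1L]
      B <- rownames(act)[act[, tumour[j]] == 1L]
      pair_tests[[paste(tumour[i], tumour[j], sep = "_vs_")]] <-
        hypergeometric_tail(n_pool, length(A), length(B),
                            length(intersect(A, B)))
    }
  }

  # family bias: union of detected instances vs genomic complement
  det_ids <- unique(unlist(lapply(annotated, function(a)
    a$instance_id[!is.na(a$instance_id)])))
  det_fams <- table(sim$repeats$family[match(det_ids,
                                             sim$repeats$instance_id)])
  bias <- family_bias(det_fams, table(sim$repeats$family))

  # expression integration on tumour-active detected loci
  tum_ids <- rownames(act)[rowSums(act[, tumour, drop = FALSE]) > 0]
  tum_loci <- sim$repeats[match(tum_ids, sim$repeats$instance_id), ,
                          drop = FALSE]
  links <- nearest_downstream_gene(tum_loci, sim$genes, promoter_upstream,
                                   promoter_downstream, max_link_distance)
  links$instance_id <- tum_loci$instance_id
  fpkm <- sim$expression$fpkm
  fc <- fold_change(rowMeans(fpkm[, tumour, drop = FALSE]),
                    rowMeans(fpkm[, control, drop = FALSE]))

  pooled_plus <- .pool_tracks(lapply(sim$expression$coverage, `[[`, "plus"))
  pooled_minus <- .pool_tracks(lapply(sim$expression$coverage, `[[`, "minus"))
  upstream_loci <- tum_loci[!is.na(links$gene_id), , drop = FALSE]
  profile <- meta_profile(upstream_loci, pooled_plus, pooled_minus)

  all_ids <- rownames(act)
  all_loci <- sim$repeats[match(all_ids, sim$repeats$instance_id), ,
                          drop = FALSE]
  link_tab <- ltr_gene_links(all_loci, sim$genes, pooled_plus,
                             pooled_minus, max_link_distance)
  link_tab$instance_id <- all_ids
  typology <- data.frame(instance_id = all_ids,
                         class = link_tab$relation,
                         planted_type = all_loci$planted_type,
                         stringsAsFactors = FALSE)

  # enrichment of upregulated genes among LTR-driven genes, per cell-line
  # pair (fold change of each tumour-like sample over each control)
  driven <- link_tab[link_tab$relation %in%
                       c("upstream_promoter", "intragenic_isoform") &
                       !is.na(link_tab$gene_id), , drop = FALSE]
  enrich_pairs <- list()
  for (t in tumour) for (cc in control) {
    fc_tc <- fold_change(fpkm[, t], fpkm[, cc])
    genes_t <- unique(driven$gene_id[act[driven$instance_id, t] == 1L])
    enrich_pairs[[paste(t, cc, sep = "_vs_")]] <-
      if (length(genes_t)) ltr_fc_enrichment(genes_t, fc_tc, up_threshold)
      else NULL
  }
  pvals <- vapply(enrich_pairs, function(e)
    if (is.null(e)) NA_real_ else e$p_value, numeric(1))
  enrich <- list(pairs = enrich_pairs, p_values = pvals,
                 max_p = max(pvals, na.rm = TRUE))

  corr <- tryCatch(
    correlation_cluster(fpkm, driven$gene_id),
    error = function(e) NULL)

  rec <- recovery_stats(sim$race$captured, annotated, min_replicates)

  res <- list(sim = sim, peaks = peaks, consensus = consensus,
              sharing = sharing, annotated = annotated, regions = regions,
              activation_matrix = act, group_sets = sets,
              dice = dmat, hclust = hc, pair_tests = pair_tests,
              family_bias = bias, links = links, gene_links = link_tab,
              fold_changes = fc,
              enrichment = enrich, meta_profile = profile,
              typology = typology, correlation = corr,
              recovery = rec, config = config)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' Write every stage output of a pipeline run
#'
#' Fixed directory layout with a verbatim YAML config echo and an md5
#' checksum manifest; two runs with the same config and seed produce
#' identical checksums.
#'
#' @param res result list from \code{\link{run_pipeline}}.
#' @param outdir output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("reads", "coverage", "peaks", "consensus", "annotation"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  sim <- res$sim
  cfg <- res$config
  cfg_plain <- unclass(cfg)
  cfg_plain$family_proportions <- as.list(cfg$family_proportions)
  cfg_plain$planted_mismatches <- as.list(cfg$planted_mismatches)
  yaml::write_yaml(cfg_plain, file.path(outdir, "config.yaml"))

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome),
    file.path(outdir, "genome.fa"))
  reps_bed <- sim$repeats[, c("chrom", "start", "end", "strand")]
  reps_bed$name <- paste(sim$repeats$instance_id, sim$repeats$family,
                         sep = "|")
  reps_bed$score <- 0
  write_bed(reps_bed, file.path(outdir, "repeats.bed"))
  write_repeatmasker_out(sim$repeats, file.path(outdir, "repeats.out"))
  write_genes_tsv(sim$genes, file.path(outdir, "genes.tsv"))
  write_expression_table(sim$expression$fpkm,
                         file.path(outdir, "expression.tsv"))
  scan <- sim$race$scan
  utils::write.table(scan, file.path(outdir, "primer_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(sim$race$reads)) {
    for (r in names(sim$race$reads[[s]]))
      write_bed(sim$race$reads[[s]][[r]],
                file.path(outdir, "reads", paste0(s, "_", r, ".bed")))
    write_bedgraph(sim$expression$coverage[[s]]$plus,
                   file.path(outdir, "coverage", paste0(s, "_plus.bedGraph")))
    write_bedgraph(sim$expression$coverage[[s]]$minus,
                   file.path(outdir, "coverage", paste0(s, "_minus.bedGraph")))
  }
  for (s in names(res$peaks)) {
    for (r in names(res$peaks[[s]]))
      write_bed(res$peaks[[s]][[r]],
                file.path(outdir, "peaks", paste0(s, "_", r, ".bed")))
    cons <- res$consensus[[s]]
    cons$name <- "."
    cons$score <- cons$support
    write_bed(cons[, c("chrom", "start", "end", "name", "score", "strand")],
              file.path(outdir, "consensus", paste0(s, ".bed")))
    ann <- res$annotated[[s]]
    ann$region <- res$regions[[s]]
    utils::write.table(ann,
                       file.path(outdir, "annotation",
                                 paste0("loci_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_bed(merge_peaksets(res$consensus[res$config$samples$tumour]),
            file.path(outdir, "merged_tumour.bed"))
  write_bed(merge_peaksets(res$consensus[res$config$samples$control]),
            file.path(outdir, "merged_control.bed"))

  utils::write.table(res$family_bias, file.path(outdir, "family_bias.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(instance_id = rownames(res$activation_matrix),
                                res$activation_matrix),
                     file.path(outdir, "activation_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = rownames(res$dice), res$dice),
                     file.path(outdir, "dice_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(dendrogram_newick(res$hclust),
             file.path(outdir, "dendrogram.nwk"))
  utils::write.table(
    data.frame(set = names(res$group_sets$counts),
               count = res$group_sets$counts),
    file.path(outdir, "group_sets.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(pair = names(res$pair_tests),
               p_value = unlist(res$pair_tests)),
    file.path(outdir, "overlap_tests.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$links, file.path(outdir, "links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(res$fold_changes),
               log2_fc = res$fold_changes),
    file.path(outdir, "fold_changes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$gene_links, file.path(outdir, "ltr_gene_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- do.call(rbind, lapply(names(res$enrichment$pairs), function(nm) {
    e <- res$enrichment$pairs[[nm]]
    if (is.null(e)) return(NULL)
    data.frame(pair = nm, population_N = e$population_N,
               successes_K = e$successes_K, draws_n = e$draws_n,
               observed_k = e$observed_k, p_value = e$p_value)
  }))
  utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(offset = res$meta_profile$offsets,
               sense = res$meta_profile$sense_mean,
               antisense = res$meta_profile$antisense_mean,
               n_loci = res$meta_profile$n_loci),
    file.path(outdir, "meta_profile.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$typology, file.path(outdir, "transcript_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$correlation)) {
    utils::write.table(
      data.frame(sample = rownames(res$correlation$correlation),
                 res$correlation$correlation),
      file.path(outdir, "correlation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(dendrogram_newick(res$correlation$hclust),
               file.path(outdir, "correlation_dendrogram.nwk"))
  }
  summary <- list(
    n_consensus_loci = nrow(res$activation_matrix),
    replicate_sharing = as.list(res$sharing),
    recovery = res$recovery,
    group_counts = as.list(res$group_sets$counts),
    enrichment_max_p = res$enrichment$max_p)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- setdiff(list.files(outdir, recursive = TRUE),
                   "manifest.md5")
  sums <- tools::md5sum(file.path(outdir, files))
  writeLines(paste(unname(sums), files), file.path(outdir, "manifest.md5"))
  invisible(outdir)
}
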