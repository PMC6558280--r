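#!/usr/bin/env Rscript
# Stage 6: integrate active LTRs with expression - nearest-downstream-gene
# links, strand-oriented metagene profile, four-way transcript typology
# (audited against the planted truth), per-cell-line fold-change enrichment
# of LTR-driven genes among upregulated genes, and correlation clustering of
# samples over LTR-linked genes.

suppressMessages(library(raceltr))

simdir <- "results/01_simulate"
cmpdir <- "results/05_compare"
outdir <- "results/06_integrate"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tumour <- c("L428", "L1236", "KMH2")
control <- c("Reh", "Namalwa")
repeats <- read_repeatmasker_out(file.path(simdir, "repeats.out"))
genes <- read_genes(file.path(simdir, "genes.tsv"), "tsv")
fpkm <- read_expression_table(file.path(simdir, "expression.tsv"))
genome <- as.character(Biostrings::readDNAStringSet(
  file.path(simdir, "genome.fa")))
glen <- genome_lengths(genome)

act_df <- utils::read.delim(file.path(cmpdir, "activation_matrix.tsv"))
act <- as.matrix(act_df[, -1])
rownames(act) <- act_df$instance_id

# pooled stranded RNA coverage across samples
tracks <- function(strand) {
  fs <- list.files(file.path(simdir, "coverage"), full.names = TRUE,
                   pattern = paste0("_", strand, "\\.bedGraph$"))
  Reduce(`+`, lapply(fs, read_bedgraph, genome_lengths = glen))
}
pp <- tracks("plus"); pm <- tracks("minus")

# oriented metagene profile: tumour-active loci upstream of a same-strand gene
tum_ids <- rownames(act)[rowSums(act[, tumour]) > 0]
tum_loci <- repeats[match(tum_ids, repeats$instance_id), ]
links <- nearest_downstream_gene(tum_loci, genes, max_distance = 50000)
links$instance_id <- tum_ids
utils::write.table(links, file.path(outdir, "links.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
prof <- meta_profile(tum_loci[!is.na(links$gene_id), ], pp, pm)
utils::write.table(data.frame(offset = prof$offsets,
                              sense = prof$sense_mean,
                              antisense = prof$antisense_mean,
                              n_loci = prof$n_loci),
                   file.path(outdir, "meta_profile.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
half <- length(prof$sense_mean) / 2
message("Metagene profile over N = ", prof$n_loci, " upstream LTRs: sense ",
        "signal downstream/upstream ratio ",
        round(mean(prof$sense_mean[(half + 1):(2 * half)]) /
                mean(prof$sense_mean[1:half]), 1),
        " - LTR-initiated transcription runs downstream on the sense strand.")

# transcript typology, audited against the planted truth
all_loci <- repeats[match(rownames(act), repeats$instance_id), ]
link_tab <- ltr_gene_links(all_loci, genes, pp, pm)
link_tab$instance_id <- rownames(act)
truth <- utils::read.delim(file.path(simdir, "truth",
                                     "planted_repeats.tsv"))
link_tab$planted_type <- truth$planted_type[match(link_tab$instance_id,
                                                  truth$instance_id)]
utils::write.table(link_tab, file.path(outdir, "transcript_classes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Transcript typology: ",
        paste(names(table(link_tab$relation)), table(link_tab$relation),
              sep = "=", collapse = ", "),
        "; agreement with planted truth ",
        round(100 * mean(link_tab$relation == link_tab$planted_type)), "%")

# enrichment of upregulated genes among LTR-driven genes, per line pair
driven <- link_tab[link_tab$relation %in%
                     c("upstream_promoter", "intragenic_isoform") &
                     !is.na(link_tab$gene_id), ]
enr <- list()
for (t in tumour) for (cc in control) {
  fc <- fold_change(fpkm[, t], fpkm[, cc])
  gset <- unique(driven$gene_id[act[driven$instance_id, t] == 1L])
  e <- ltr_fc_enrichment(gset, fc, up_threshold = 1)
  enr[[paste(t, cc, sep = "_vs_")]] <-
    data.frame(pair = paste(t, cc, sep = "_vs_"),
               population_N = e$population_N, successes_K = e$successes_K,
               draws_n = e$draws_n, observed_k = e$observed_k,
               p_value = e$p_value)
}
enr <- do.call(rbind, enr)
utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("LTR-driven genes vs upregulated genes (hypergeometric): max p = ",
        signif(max(enr$p_value), 3),
        if (max(enr$p_value) < 0.01) " - significant for every pair" else "")

# correlation clustering of samples over LTR-linked genes
cc <- correlation_cluster(fpkm, driven$gene_id)
utils::write.table(data.frame(sample = rownames(cc$correlation),
                              cc$correlation),
                   file.path(outdir, "correlation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(dendrogram_newick(cc$hclust),
           file.path(outdir, "correlation_dendrogram.nwk"))
message("Expression of LTR-linked genes clusters tumour samples together: ",
        clades_separate_groups(cc$hclust, tumour, control))
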