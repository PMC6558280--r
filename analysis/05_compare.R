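#!/usr/bin/env Rscript
# Stage 5: cross-sample comparison of active LTR repertoires - activation
# matrix, tumour/control-specific and shared counts, pairwise overlap
# significance (hypergeometric), and Dice-index clustering of samples.

suppressMessages(library(raceltr))

simdir <- "results/01_simulate"
anndir <- "results/04_annotate"
outdir <- "results/05_compare"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tumour <- c("L428", "L1236", "KMH2")
control <- c("Reh", "Namalwa")
repeats <- read_repeatmasker_out(file.path(simdir, "repeats.out"))

ann_files <- list.files(anndir, pattern = "^loci_", full.names = TRUE)
annotated <- lapply(ann_files, utils::read.delim)
names(annotated) <- sub("^loci_(.*)\\.tsv$", "\\1", basename(ann_files))
annotated <- annotated[c(tumour, control)]

act <- build_activation_matrix(annotated, repeats)
utils::write.table(data.frame(instance_id = rownames(act), act),
                   file.path(outdir, "activation_matrix.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

sets <- group_specific_sets(act, tumour, control)
utils::write.table(data.frame(set = names(sets$counts),
                              count = sets$counts),
                   file.path(outdir, "group_sets.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Active-locus universe: ", nrow(act), " loci. ",
        "Tumour-specific ", sets$counts["a_specific"],
        ", control-specific ", sets$counts["b_specific"],
        ", shared within tumour ", sets$counts["shared_within_a"],
        " (unique to tumour ", sets$counts["unique_to_a"], ").")

# population for the overlap test: the pool active sets are drawn from,
# i.e. every amplifiable instance (the detected union would condition on
# the outcome and mask shared cores)
scan <- utils::read.delim(
  file.path("results/02_scan_primer", "primer_scan.tsv"))
n_pool <- sum(scan$amplifiable)
pairs <- utils::combn(tumour, 2)
ptab <- apply(pairs, 2, function(p) {
  A <- rownames(act)[act[, p[1]] == 1L]
  B <- rownames(act)[act[, p[2]] == 1L]
  hypergeometric_tail(n_pool, length(A), length(B),
                      length(intersect(A, B)))
})
utils::write.table(data.frame(pair = apply(pairs, 2, paste,
                                           collapse = "_vs_"),
                              p_value = ptab),
                   file.path(outdir, "overlap_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Pairwise tumour overlap hypergeometric p: ",
        paste(signif(ptab, 3), collapse = ", "),
        if (all(ptab < 0.01)) " - all significant (p < 0.01)" else "")

dm <- dice_matrix(act)
utils::write.table(data.frame(sample = rownames(dm), dm),
                   file.path(outdir, "dice_matrix.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
hc <- cluster_similarity(dm)
writeLines(dendrogram_newick(hc), file.path(outdir, "dendrogram.nwk"))
message("Dice clustering: tumour-like samples form their own clade: ",
        clades_separate_groups(hc, tumour, control))
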