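#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study - a 2 Mb genome with 300 planted
# MaLR LTR instances (THE1A-D, MSTA, MSTB), 240 genes, tumour/control
# activation states, triplicate RACE-Seq reads with capture dropout, and
# stranded expression data. Ground truth is written alongside so later
# stages can audit themselves; everything is deterministic under the seed.

suppressMessages(library(raceltr))

seed <- as.integer(Sys.getenv("RACELTR_SEED", "1"))
outdir <- "results/01_simulate"
dir.create(file.path(outdir, "reads"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(outdir, "coverage"), showWarnings = FALSE)
dir.create(file.path(outdir, "truth"), showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)

cfg_plain <- unclass(cfg)
cfg_plain$family_proportions <- as.list(cfg$family_proportions)
cfg_plain$planted_mismatches <- as.list(cfg$planted_mismatches)
yaml::write_yaml(cfg_plain, file.path(outdir, "config.yaml"))
writeLines(sim$primer, file.path(outdir, "primer.txt"))

Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                            file.path(outdir, "genome.fa"))
write_repeatmasker_out(sim$repeats, file.path(outdir, "repeats.out"))
write_genes_tsv(sim$genes, file.path(outdir, "genes.tsv"))
write_expression_table(sim$expression$fpkm,
                       file.path(outdir, "expression.tsv"))
for (s in names(sim$race$reads)) {
  for (r in names(sim$race$reads[[s]]))
    write_bed(sim$race$reads[[s]][[r]],
              file.path(outdir, "reads", paste0(s, "_", r, ".bed")))
  write_bedgraph(sim$expression$coverage[[s]]$plus,
                 file.path(outdir, "coverage", paste0(s, "_plus.bedGraph")))
  write_bedgraph(sim$expression$coverage[[s]]$minus,
                 file.path(outdir, "coverage", paste0(s, "_minus.bedGraph")))
}

# synthetic ground truth (planted transcript types, activation, capture)
utils::write.table(
  sim$repeats[, c("instance_id", "family", "planted_type",
                  "planted_mismatches", "assoc_gene")],
  file.path(outdir, "truth", "planted_repeats.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(instance_id = rownames(sim$activation), sim$activation),
  file.path(outdir, "truth", "activation.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cap <- sim$race$captured
cap_df <- do.call(rbind, lapply(dimnames(cap)[[2]], function(s)
  data.frame(instance_id = dimnames(cap)[[1]], sample = s,
             n_replicates_captured = rowSums(cap[, s, , drop = FALSE]))))
utils::write.table(cap_df, file.path(outdir, "truth", "capture.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

n_active <- colSums(sim$activation)
message("Simulated ", sum(nchar(sim$genome)), " bp over ",
        length(sim$genome), " chromosomes; ", nrow(sim$repeats),
        " LTR instances, ", nrow(sim$genes), " genes.")
message("Active loci per sample: ",
        paste(names(n_active), n_active, sep = "=", collapse = ", "))
message("Outputs in ", outdir)
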