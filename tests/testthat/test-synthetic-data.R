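test_that("config validation enforces proportions, probabilities and seed", {
  expect_error(sim_config(family_proportions = c(THE1B = 0.5, MSTA = 0.4)),
               "sum to 1")
  expect_error(sim_config(replicate_dropout = 1.5), "probabilities")
  expect_error(sim_config(seed = 2^31), "seed")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("build_genome is deterministic and honours divergence", {
  cfg <- tiny_config(seed = 7)
  g1 <- build_genome(cfg)
  g2 <- build_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$repeats, g2$repeats)
  expect_identical(g1$genes, g2$genes)

  cfg0 <- tiny_config(seed = 7, divergence_rate = 0)
  g0 <- build_genome(cfg0)
  # zero divergence: every instance is its family consensus (after strand)
  for (i in seq_len(nrow(g0$repeats))) {
    r <- g0$repeats[i, ]
    seq <- substr(g0$genome[[r$chrom]], r$start + 1, r$end)
    if (r$strand == "-") seq <- oracle_revcomp(seq)
    expect_identical(seq, g0$consensus[[r$family]])
  }
  expect_true(all(g0$repeats$planted_mismatches ==
                    cfg0$planted_mismatches[g0$repeats$family]))
})

test_that("a repeat-free genome still places genes; capacity errors raised", {
  cfg <- tiny_config(seed = 3, n_repeats = 0, n_genes = 10)
  g <- build_genome(cfg)
  expect_equal(nrow(g$repeats), 0L)
  expect_equal(nrow(g$genes), 10L)
  expect_error(build_genome(tiny_config(seed = 3, genome_length = 5e4)),
               "capacity")
})

test_that("planted features are internally consistent", {
  gen <- build_genome(tiny_config(seed = 13))
  reps <- gen$repeats
  genes <- gen$genes
  expect_equal(anyDuplicated(reps$instance_id), 0L)
  expect_setequal(unique(reps$planted_type),
                  c("upstream_promoter", "intragenic_isoform", "antisense",
                    "intergenic_lncRNA"))
  # genes: tss invariant and two sorted non-overlapping exons inside the body
  exons <- attr(genes, "exons")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    expect_equal(g$tss, if (g$strand == "+") g$start else g$end - 1L)
    ex <- exons[[g$gene_id]]
    expect_true(all(ex$start >= g$start & ex$end <= g$end))
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end[-nrow(ex)] <= ex$start[-1]))
  }
  # repeats do not overlap one another
  ov <- gi_overlaps(reps, reps)
  expect_true(all(ov$query == ov$subject))
  # upstream-promoter loci sit outside their gene's promoter window
  t1 <- reps[reps$planted_type == "upstream_promoter", ]
  regions_t1 <- annotate_genomic_region(t1, genes)
  expect_true(all(regions_t1 != "TSS_promoter"))
})

test_that("activation has the planted group structure", {
  cfg <- tiny_config(seed = 9)
  gen <- build_genome(cfg)
  groups <- cfg$samples
  cfg1 <- cfg; cfg1$activation$tumour$shared_fraction <- 1
  m1 <- assign_activation(gen$repeats, groups, cfg1)
  tum <- groups$tumour
  expect_true(all(m1[, tum[1]] == m1[, tum[2]]) &&
                all(m1[, tum[1]] == m1[, tum[3]]))

  m <- assign_activation(gen$repeats, groups, cfg)
  on_t <- rowSums(m[, groups$tumour]) > 0
  on_c <- rowSums(m[, groups$control]) > 0
  expect_equal(sum(on_t & on_c), 0L)   # disjoint pools
  expect_identical(m, assign_activation(gen$repeats, groups, cfg))

  # shared fraction 0: pairwise overlap of private draws stays near the
  # sampling expectation (direct count over the generated matrix)
  cfg0 <- cfg; cfg0$activation$tumour$shared_fraction <- 0
  m0 <- assign_activation(gen$repeats, groups, cfg0)
  n_active <- sum(m0[, tum[1]])
  pool <- sum(rowSums(m0[, tum]) > 0)  # lower bound on pool size
  obs <- sum(m0[, tum[1]] & m0[, tum[2]])
  expect_lt(obs, n_active)             # far from fully shared
  expect_error(
    assign_activation(gen$repeats, groups,
                      tiny_config(seed = 9, activation = list(
                        tumour = list(active_fraction = 0.9,
                                      shared_fraction = 0.5),
                        control = list(active_fraction = 0.9,
                                       shared_fraction = 0.5)))),
    "capacity")
})

test_that("read simulation obeys activation, primer budget and dropout", {
  cfg <- tiny_config(seed = 17, replicate_dropout = 0)
  gen <- build_genome(cfg)
  act <- assign_activation(gen$repeats, cfg$samples, cfg)
  race <- simulate_race_reads(gen$genome, gen$repeats, act, gen$primer, cfg)
  amp <- race$scan$amplifiable
  # dropout 0: every active amplifiable locus captured in all replicates
  for (s in colnames(act)) {
    expected <- act[, s] == 1L & amp
    for (r in dimnames(race$captured)[[3]])
      expect_equal(unname(race$captured[, s, r]), unname(expected))
    # read-count conservation
    for (rd in race$reads[[s]])
      expect_equal(nrow(rd),
                   sum(expected) * cfg$reads_per_active_ltr +
                     cfg$background_reads)
  }
  # all-zero activation: only background reads
  act0 <- act; act0[] <- 0L
  race0 <- simulate_race_reads(gen$genome, gen$repeats, act0, gen$primer,
                               cfg)
  expect_equal(nrow(race0$reads[[1]][[1]]), cfg$background_reads)
  # determinism
  race2 <- simulate_race_reads(gen$genome, gen$repeats, act, gen$primer, cfg)
  expect_identical(race$reads, race2$reads)
})

test_that("a locus with >8 primer-window mismatches yields no reads", {
  cfg <- tiny_config(seed = 23, background_reads = 0,
                     replicate_dropout = 0)
  gen <- build_genome(cfg)
  # corrupt one instance: 9 substitutions inside the primer window
  r <- gen$repeats[1, ]
  seq <- substr(gen$genome[[r$chrom]], r$start + 1, r$end)
  inst <- if (r$strand == "-") oracle_revcomp(seq) else seq
  ch <- strsplit(inst, "")[[1]]
  pw <- cfg$primer_offset
  pr <- strsplit(gen$primer, "")[[1]]
  for (j in 1:9)   # force disagreement with the primer at 9 positions
    ch[pw + j] <- setdiff(c("A", "C", "G", "T"), pr[j])[1]
  inst2 <- paste(ch, collapse = "")
  mm <- count_mismatches(gen$primer, substr(inst2, pw + 1, pw + nchar(gen$primer)))
  expect_gt(mm, 8)
  gseq <- if (r$strand == "-") oracle_revcomp(inst2) else inst2
  substr(gen$genome[[r$chrom]], r$start + 1, r$end) <- gseq
  act <- matrix(1L, nrow(gen$repeats), 1,
                dimnames = list(gen$repeats$instance_id, "s1"))
  race <- simulate_race_reads(gen$genome, gen$repeats, act, gen$primer, cfg)
  hits <- gi_overlaps(race$reads$s1$rep1, gen$repeats[1, , drop = FALSE])
  expect_equal(nrow(hits), 0L)
})

test_that("expression boost multiplies FPKM of LTR-driven genes", {
  cfg <- tiny_config(seed = 31, noise_log_sd = 0)
  gen <- build_genome(cfg)
  act <- assign_activation(gen$repeats, cfg$samples, cfg)
  glen <- genome_lengths(gen$genome)
  ex <- simulate_expression(gen$genes, gen$repeats, act, cfg,
                            chrom_lengths = glen)
  driven <- gen$repeats[!is.na(gen$repeats$assoc_gene), ]
  hit <- driven[act[driven$instance_id, "L428"] == 1L, ][1, ]
  off_sample <- colnames(act)[act[hit$instance_id, ] == 0L][1]
  # noiseless ratio is exactly the boost
  expect_equal(ex$fpkm[hit$assoc_gene, "L428"] /
                 ex$fpkm[hit$assoc_gene, off_sample],
               cfg$ltr_expression_boost)
  # boost 1: tracks of both groups drawn from the same law; same seed gives
  # identical tables
  cfg1 <- tiny_config(seed = 31, noise_log_sd = 0, ltr_expression_boost = 1)
  ex1a <- simulate_expression(gen$genes, gen$repeats, act, cfg1,
                              chrom_lengths = glen)
  ex1b <- simulate_expression(gen$genes, gen$repeats, act, cfg1,
                              chrom_lengths = glen)
  expect_identical(ex1a$fpkm, ex1b$fpkm)
  expect_equal(unname(ex1a$fpkm[, "L428"]), unname(ex1a$fpkm[, "Reh"]))
})

test_that("inactive LTRs emit no LTR-originating coverage", {
  cfg <- tiny_config(seed = 37)
  gen <- build_genome(cfg)
  act <- assign_activation(gen$repeats, cfg$samples, cfg)
  glen <- genome_lengths(gen$genome)
  ex <- simulate_expression(gen$genes, gen$repeats, act, cfg,
                            chrom_lengths = glen)
  # an inactive lncRNA-type locus overlaps no gene, so its sense track must
  # be flat zero at the locus
  lnc <- gen$repeats[gen$repeats$planted_type == "intergenic_lncRNA", ]
  s <- colnames(act)[1]
  idle <- lnc[act[lnc$instance_id, s] == 0L, ][1, ]
  track <- if (idle$strand == "+") ex$coverage[[s]]$plus
           else ex$coverage[[s]]$minus
  v <- as.numeric(S4Vectors::window(track[[idle$chrom]], idle$start + 1,
                                    idle$end))
  expect_true(all(v == 0))
})
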