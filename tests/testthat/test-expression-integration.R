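test_that("FPKM follows the counts formula", {
  counts <- matrix(c(100, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  f <- compute_fpkm(counts, gene_lengths = c(1000, 500),
                    library_sizes = 1e7)
  expect_equal(f["g1", "s1"], 10)
  expect_equal(f["g2", "s1"], 0)
  # doubling the library size halves FPKM
  f2 <- compute_fpkm(counts, c(1000, 500), 2e7)
  expect_equal(f2, f / 2)
  expect_error(compute_fpkm(counts, c(0, 500), 1e7), "positive")
  expect_error(compute_fpkm(counts, c(1000, 500), 0), "positive")
})

test_that("fold change is log2 with pseudocount and antisymmetric", {
  a <- c(g1 = 7, g2 = 3)
  b <- c(g1 = 1, g2 = 3)
  fc <- fold_change(a, b)
  expect_equal(unname(fc["g1"]), 2)
  expect_equal(unname(fc["g2"]), 0)
  expect_equal(fold_change(a, b), -fold_change(b, a))
  expect_error(fold_change(a, c(g1 = 1, g3 = 2)), "universes")
})

up_genes <- function() {
  g <- gintervals(chrom = rep("chr1", 2), start = c(5000L, 9000L),
                  end = c(8000L, 12000L), strand = "+",
                  gene_id = c("gA", "gB"))
  g$tss <- g$start
  g
}

test_that("nearest downstream gene honours strand and promoter exclusion", {
  genes <- up_genes()
  locus <- gintervals(chrom = "chr1", start = 1000L, end = 1350L,
                      strand = "+")
  link <- nearest_downstream_gene(locus, genes)
  expect_equal(link$gene_id, "gA")
  expect_equal(link$distance, 3650)
  # mirrored '-' geometry: reflect everything through L = 13000
  L <- 13000L
  genes_m <- gintervals(chrom = rep("chr1", 2),
                        start = L - c(8000L, 12000L),
                        end = L - c(5000L, 9000L), strand = "-",
                        gene_id = c("gA", "gB"))
  genes_m$tss <- genes_m$end - 1L
  locus_m <- gintervals(chrom = "chr1", start = L - 1350L, end = L - 1000L,
                        strand = "-")
  link_m <- nearest_downstream_gene(locus_m, genes_m)
  expect_equal(link_m$gene_id, "gA")
  expect_equal(link_m$distance, 3650)
  # locus inside a promoter window is excluded
  prom_locus <- gintervals(chrom = "chr1", start = 4200L, end = 4400L,
                           strand = "+")
  expect_true(is.na(nearest_downstream_gene(prom_locus, genes)$gene_id))
  # unstranded locus is an error
  expect_error(nearest_downstream_gene(
    gintervals(chrom = "chr1", start = 0L, end = 10L, strand = "."), genes),
    "strand")
})

test_that("strand-mirror symmetry holds on random gene layouts", {
  set.seed(59)
  L <- 100000L
  for (i in 1:20) {
    gs <- sort(sample(seq(10000L, 80000L, by = 100L), 4))
    genes <- gintervals(chrom = rep("chr1", 4), start = gs,
                        end = gs + 3000L, strand = "+",
                        gene_id = paste0("g", 1:4))
    genes$tss <- genes$start
    locus <- gintervals(chrom = "chr1", start = 2000L, end = 2350L,
                        strand = "+")
    fw <- nearest_downstream_gene(locus, genes)
    genes_m <- gintervals(chrom = rep("chr1", 4), start = L - (gs + 3000L),
                          end = L - gs, strand = "-",
                          gene_id = paste0("g", 1:4))
    genes_m$tss <- genes_m$end - 1L
    locus_m <- gintervals(chrom = "chr1", start = L - 2350L, end = L - 2000L,
                          strand = "-")
    mr <- nearest_downstream_gene(locus_m, genes_m)
    expect_equal(mr$gene_id, fw$gene_id)
    expect_equal(mr$distance, fw$distance)
  }
})

flat_tracks <- function(L, plus = numeric(L), minus = numeric(L)) {
  list(plus = IRanges::RleList(chr1 = S4Vectors::Rle(plus)),
       minus = IRanges::RleList(chr1 = S4Vectors::Rle(minus)))
}

test_that("meta profiles orient by locus strand and conserve signal", {
  L <- 4000L
  plus <- numeric(L); plus[2001:2600] <- 3   # signal right of centre
  tr <- flat_tracks(L, plus = plus)
  locus <- gintervals(chrom = "chr1", start = 1950L, end = 2050L,
                      strand = "+")
  mp <- meta_profile(locus, tr$plus, tr$minus, window = 2000, binsize = 50)
  half <- length(mp$sense_mean) / 2
  expect_equal(mp$n_loci, 1L)
  expect_true(all(mp$sense_mean[1:half] == 0))
  expect_true(sum(mp$sense_mean[(half + 1):(2 * half)]) > 0)
  expect_true(all(mp$antisense_mean == 0))
  # conservation: bin means times binsize reproduce the raw extracted sum
  expect_equal(sum(mp$sense_mean + mp$antisense_mean) * 50,
               sum(plus[(2000 - 1000 + 1):(2000 + 1000)]))
  # same signal, locus relabelled '-': mirrored and moved to antisense
  locus_m <- locus; locus_m$strand <- "-"
  mp_m <- meta_profile(locus_m, tr$plus, tr$minus, window = 2000,
                       binsize = 50)
  expect_equal(mp_m$antisense_mean, rev(mp$sense_mean))
  expect_true(all(mp_m$sense_mean == 0))
  # averaging two identical loci changes nothing
  mp2 <- meta_profile(rbind(locus, locus), tr$plus, tr$minus,
                      window = 2000, binsize = 50)
  expect_equal(mp2$sense_mean, mp$sense_mean)
  # out-of-bounds window is skipped and counted
  edge <- gintervals(chrom = "chr1", start = 10L, end = 60L, strand = "+")
  mp3 <- meta_profile(rbind(locus, edge), tr$plus, tr$minus,
                      window = 2000, binsize = 50)
  expect_equal(mp3$n_loci, 1L)
  expect_equal(mp3$n_skipped, 1L)
  expect_error(meta_profile(locus, tr$plus, tr$minus, window = 1975,
                            binsize = 50), "multiple")
})

test_that("transcript classification recovers all planted types", {
  cfg <- tiny_config(seed = 61)
  sim <- simulate_dataset(cfg)
  glen <- genome_lengths(sim$genome)
  pooled_plus <- Reduce(`+`, lapply(sim$expression$coverage, `[[`, "plus"))
  pooled_minus <- Reduce(`+`, lapply(sim$expression$coverage, `[[`, "minus"))
  active <- rownames(sim$activation)[rowSums(sim$activation) > 0]
  loci <- sim$repeats[match(active, sim$repeats$instance_id), ]
  cls <- classify_ltr_transcript(loci, sim$genes, pooled_plus, pooled_minus)
  expect_equal(cls, loci$planted_type)
  # labels partition the classified loci
  expect_true(all(cls %in% c("upstream_promoter", "intragenic_isoform",
                             "antisense", "intergenic_lncRNA")))
  links <- ltr_gene_links(loci, sim$genes, pooled_plus, pooled_minus)
  expect_equal(links$relation, cls)
  driven <- links$relation %in% c("upstream_promoter", "intragenic_isoform")
  expect_equal(links$gene_id[driven], loci$assoc_gene[driven])
  expect_true(all(is.na(links$gene_id[links$relation ==
                                        "intergenic_lncRNA"])))
  expect_error(classify_ltr_transcript(
    gintervals(chrom = "chr1", start = 0L, end = 10L, strand = "."),
    sim$genes, pooled_plus, pooled_minus), "stranded")
})

test_that("enrichment counts and trivial cases are exact", {
  fc <- stats::setNames(c(2, 2, 0, 0, 0, 0, 0, 0, 0, 0), paste0("g", 1:10))
  res <- ltr_fc_enrichment(c("g1", "g2"), fc, up_threshold = 1)
  expect_equal(res$observed_k, 2L)
  expect_equal(res$p_value, oracle_hyper_tail(10, 2, 2, 2))
  # no upregulated linked genes: p = 1
  res0 <- ltr_fc_enrichment(c("g5", "g6"), fc)
  expect_equal(res0$observed_k, 0L)
  expect_equal(res0$p_value, 1)
  expect_error(ltr_fc_enrichment(character(), fc), "empty")
  expect_error(ltr_fc_enrichment("nope", fc), "missing")
})

test_that("correlation clustering groups duplicated and anti-correlated columns", {
  set.seed(67)
  base <- exp(stats::rnorm(20, log(10), 1))
  fpkm <- cbind(s1 = base, s2 = base,
                s3 = exp(stats::rnorm(20, log(10), 1)))
  rownames(fpkm) <- paste0("g", 1:20)
  cc <- correlation_cluster(fpkm, paste0("g", 1:20))
  expect_equal(cc$correlation["s1", "s2"], 1)
  first <- sort(cc$hclust$labels[-cc$hclust$merge[1, ]])
  expect_equal(first, c("s1", "s2"))
  # anti-correlated constructed columns
  x <- seq_len(20)
  m <- cbind(a = 2^x - 1, b = 2^rev(x) - 1, c = 2^sample(x) - 1)
  rownames(m) <- paste0("g", 1:20)
  cc2 <- correlation_cluster(m, paste0("g", 1:20))
  expect_equal(cc2$correlation["a", "b"], -1)
  flat <- cbind(s1 = rep(1, 5), s2 = seq_len(5))
  rownames(flat) <- paste0("g", 1:5)
  expect_error(correlation_cluster(flat, paste0("g", 1:5)), "s1")
})
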