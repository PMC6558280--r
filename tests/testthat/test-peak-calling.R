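test_that("compute_coverage counts overlapping reads per base", {
  glen <- c(chr1 = 30L)
  one <- gintervals(chrom = "chr1", start = 10L, end = 20L)
  cov <- compute_coverage(one, glen)
  expect_equal(as.numeric(cov$chr1), c(rep(0, 10), rep(1, 10), rep(0, 10)))
  two <- rbind(one, one)
  expect_equal(max(compute_coverage(two, glen)$chr1), 2)
  empty <- gintervals()
  expect_equal(sum(compute_coverage(empty, glen)$chr1), 0)
  oob <- gintervals(chrom = "chr1", start = 25L, end = 35L)
  expect_error(compute_coverage(oob, glen), "bounds")
})

cov_track <- function(v) {
  IRanges::RleList(chr1 = S4Vectors::Rle(v))
}

test_that("call_peaks applies threshold, merge and width rules", {
  cov <- cov_track(c(0, 0, 5, 5, 5, 0, 0))
  pk <- call_peaks(cov, min_height = 1, merge_gap = 0, min_width = 1)
  expect_equal(pk[, c("start", "end")],
               data.frame(start = 2L, end = 5L))
  # two runs separated by a single low base, merge_gap 2 -> one peak
  cov2 <- cov_track(c(5, 5, 0, 5, 5))
  pk2 <- call_peaks(cov2, min_height = 5, merge_gap = 2, min_width = 1)
  expect_equal(nrow(pk2), 1L)
  expect_equal(c(pk2$start, pk2$end), c(0L, 5L))
  pk2b <- call_peaks(cov2, min_height = 5, merge_gap = 1, min_width = 1)
  expect_equal(nrow(pk2b), 2L)
  # nothing above threshold
  expect_equal(nrow(call_peaks(cov_track(rep(1, 10)), min_height = 5,
                               merge_gap = 0, min_width = 1)), 0L)
  expect_error(call_peaks(cov, min_height = 0, merge_gap = 0, min_width = 1),
               "invalid")
})

test_that("call_peaks equals the exhaustive run-enumeration oracle", {
  set.seed(41)
  for (i in 1:300) {
    L <- sample(20:200, 1)
    v <- stats::rpois(L, lambda = sample(1:4, 1))
    h <- sample(1:5, 1); g <- sample(0:10, 1); w <- sample(1:20, 1)
    got <- call_peaks(cov_track(v), h, g, w)
    ora <- oracle_call_peaks(v, h, g, w)
    expect_equal(got$start, ora$start)
    expect_equal(got$end, ora$end)
  }
})

test_that("lowering min_height never removes covered bases", {
  set.seed(43)
  for (i in 1:30) {
    v <- stats::rpois(150, 3)
    hi <- call_peaks(cov_track(v), 4, 5, 3)
    lo <- call_peaks(cov_track(v), 2, 5, 3)
    base_cov <- function(p) {
      out <- rep(FALSE, 150)
      for (j in seq_len(nrow(p))) out[(p$start[j] + 1):p$end[j]] <- TRUE
      out
    }
    expect_true(all(!base_cov(hi) | base_cov(lo)))
  }
})

test_that("replicate consensus keeps 2-of-3 regions and drops singletons", {
  pk <- function(s, e) gintervals(chrom = "chr1", start = s, end = e)
  same <- pk(100L, 200L)
  other <- pk(400L, 450L)
  cons <- replicate_consensus(list(same, same, other), min_replicates = 2)
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(100L, 200L))
  expect_equal(cons$support, 2L)
  # present in one replicate only: absent
  cons1 <- replicate_consensus(list(same, other, pk(700L, 750L)),
                               min_replicates = 2)
  expect_equal(nrow(cons1), 0L)
  # staggered peaks sharing a core
  st <- replicate_consensus(list(pk(0L, 120L), pk(50L, 170L), pk(100L, 220L)),
                            min_replicates = 2)
  ora <- oracle_consensus(list(pk(0L, 120L), pk(50L, 170L), pk(100L, 220L)),
                          300L, 2)
  expect_equal(st$start, ora$start)
  expect_equal(st$end, ora$end)
  expect_equal(st$support, ora$support)
  expect_error(replicate_consensus(list(same), min_replicates = 2),
               "min_replicates")
})

test_that("replicate consensus equals a per-base depth oracle and is order-invariant", {
  set.seed(47)
  for (i in 1:200) {
    sets <- lapply(1:3, function(j) random_peakset(200L, sample(0:5, 1)))
    mr <- sample(1:3, 1)
    got <- replicate_consensus(sets, mr)
    ora <- oracle_consensus(sets, 200L, mr)
    expect_equal(got$start, ora$start)
    expect_equal(got$end, ora$end)
    expect_equal(got$support, ora$support)
    perm <- replicate_consensus(sets[c(3, 1, 2)], mr)
    expect_equal(got[, c("start", "end", "support")],
                 perm[, c("start", "end", "support")])
  }
})

test_that("merge_peaksets unions and coalesces intervals", {
  a <- gintervals(chrom = "chr1", start = 10L, end = 20L)
  b <- gintervals(chrom = "chr1", start = 15L, end = 30L)
  m <- merge_peaksets(list(a, b))
  expect_equal(c(m$start, m$end), c(10L, 30L))
  # idempotence
  expect_equal(merge_peaksets(list(a, a))[, c("start", "end")],
               a[, c("start", "end")])
  # disjoint sets concatenate sorted
  c2 <- gintervals(chrom = c("chr1", "chr2"), start = c(100L, 5L),
                   end = c(120L, 9L))
  m2 <- merge_peaksets(list(a, c2))
  expect_equal(m2$start, c(10L, 100L, 5L))
})

test_that("replicate_sharing reports the all-replicate fraction", {
  pk <- function(s, e) gintervals(chrom = "chr1", start = s, end = e)
  sets <- list(rbind(pk(0L, 50L), pk(100L, 150L)),
               rbind(pk(0L, 50L), pk(100L, 150L)),
               pk(0L, 50L))
  expect_equal(replicate_sharing(sets), 0.5)
  expect_true(is.na(replicate_sharing(list(gintervals(), gintervals()))))
})
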