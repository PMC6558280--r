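test_that("activation matrix spans the union of hit instances", {
  ann <- function(ids) data.frame(instance_id = ids,
                                  family = "THE1B",
                                  stringsAsFactors = FALSE)
  reps <- gintervals(chrom = rep("chr1", 3), start = c(0L, 500L, 900L),
                     end = c(350L, 850L, 1250L),
                     instance_id = c("r1", "r2", "r3"), family = "THE1B")
  m <- build_activation_matrix(list(s1 = ann(c("r1", "r2")),
                                    s2 = ann("r3")), reps)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m[, "s1"]), c(1L, 1L, 0L))
  expect_equal(unname(m[, "s2"]), c(0L, 0L, 1L))
  # single sample, two loci
  m1 <- build_activation_matrix(list(s1 = ann(c("r1", "r2"))), reps)
  expect_equal(unname(m1[, 1]), c(1L, 1L))
})

test_that("group-specific sets follow merged-peak semantics", {
  m <- matrix(0L, 5, 5,
              dimnames = list(paste0("l", 1:5),
                              c("t1", "t2", "t3", "c1", "c2")))
  m["l1", c("t1", "t2", "t3")] <- 1L          # shared within tumour, unique
  m["l2", "t1"] <- 1L                          # tumour-private
  m["l3", c("t1", "c1")] <- 1L                 # shared across groups
  m["l4", "c1"] <- 1L                          # control-private
  m["l5", c("c1", "c2")] <- 1L                 # shared within control
  s <- group_specific_sets(m, c("t1", "t2", "t3"), c("c1", "c2"))
  expect_setequal(s$a_specific, c("l1", "l2"))
  expect_setequal(s$b_specific, c("l4", "l5"))
  expect_equal(s$shared, "l3")
  expect_equal(s$shared_within_a, "l1")
  expect_equal(s$unique_to_a, "l1")
  expect_setequal(s$shared_within_b, "l5")
  # identical activity in both groups: no specific loci
  m2 <- m; m2[, ] <- 1L
  s2 <- group_specific_sets(m2, c("t1", "t2", "t3"), c("c1", "c2"))
  expect_equal(length(s2$a_specific), 0L)
  expect_equal(length(s2$b_specific), 0L)
  # permutation invariance within groups
  s3 <- group_specific_sets(m, c("t3", "t1", "t2"), c("c2", "c1"))
  expect_equal(s$counts, s3$counts)
  expect_error(group_specific_sets(m, c("t1", "c1"), c("c1")), "disjoint")
})

test_that("dice_index matches the formula and its properties", {
  expect_equal(dice_index(letters[1:7], letters[1:7]), 1)
  expect_equal(dice_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(dice_index(c("a", "b", "c", "d"),
                          c("a", "b", "x", "y", "z", "w")), 0.4)
  expect_error(dice_index(character(), character()), "undefined")
  set.seed(53)
  for (i in 1:300) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    d <- dice_index(a, b)
    expect_equal(d, dice_index(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d == 1, setequal(a, b))
    # brute-force intersection arithmetic
    expect_equal(d, 2 * sum(unique(a) %in% unique(b)) /
                   (length(unique(a)) + length(unique(b))))
  }
})

test_that("similarity clustering merges identical samples first", {
  m <- matrix(0L, 6, 5,
              dimnames = list(paste0("l", 1:6), paste0("s", 1:5)))
  m[1:3, "s1"] <- 1L; m[1:3, "s2"] <- 1L       # identical pair
  m[4, "s3"] <- 1L; m[5, "s4"] <- 1L; m[6, "s5"] <- 1L
  d <- dice_matrix(m)
  expect_equal(d["s1", "s2"], 1)
  expect_true(isSymmetric(d))
  hc <- cluster_similarity(d)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("s1", "s2"))
  expect_equal(hc$height[1], 0)
  # all pairwise scores equal -> equal merge heights
  deq <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(deq) <- 1
  expect_equal(length(unique(round(cluster_similarity(deq)$height, 12))), 1L)
  expect_error(cluster_similarity(deq[1, 1, drop = FALSE]), "at least 2")
})

test_that("hypergeometric tail matches exact enumeration", {
  expect_equal(hypergeometric_tail(10, 5, 4, 0), 1)
  expect_equal(hypergeometric_tail(10, 5, 4, 4), 5 / 210)
  expect_equal(hypergeometric_tail(10, 5, 4, 4),
               oracle_hyper_tail(10, 5, 4, 4))
  # full tail sums to 1 via the k = 0 term; P(X >= 0) == 1 by definition,
  # and summing the pmf over the support returns 1
  N <- 20; K <- 10; n <- 10
  pmf <- vapply(0:10, function(k)
    hypergeometric_tail(N, K, n, k) -
      if (k < 10) hypergeometric_tail(N, K, n, k + 1) else 0,
    numeric(1))
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # agreement with the independent stats implementation
  for (k in 0:10)
    expect_equal(hypergeometric_tail(N, K, n, k),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  expect_error(hypergeometric_tail(10, 11, 4, 2), "impossible")
  expect_error(hypergeometric_tail(10, 5, 4, 5), "impossible")
})

test_that("clade separation check reads the 2-cut of the dendrogram", {
  d <- diag(5); dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  d[1:3, 1:3] <- 0.8; d[4:5, 4:5] <- 0.8; diag(d) <- 1
  hc <- cluster_similarity(d)
  expect_true(clades_separate_groups(hc, paste0("s", 1:3), paste0("s", 4:5)))
  expect_false(clades_separate_groups(hc, paste0("s", c(1, 2, 4)),
                                      paste0("s", c(3, 5))))
})
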