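# Small, fast simulation used by module tests (full defaults are exercised in
# the acceptance suite). 40 repeats = 10 planted loci of each transcript
# type; capacity ~250 kb on one chromosome.
tiny_config <- function(...) {
  args <- list(genome_length = 3e5, n_chroms = 1, n_repeats = 40,
               n_genes = 32, reads_per_active_ltr = 50,
               background_reads = 200,
               activation = list(
                 tumour = list(active_fraction = 0.4, shared_fraction = 0.6),
                 control = list(active_fraction = 0.2,
                                shared_fraction = 0.6)))
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Independent reverse complement (no Biostrings) for oracle code.
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Brute-force primer scan oracle: naive loop over offsets, naive per-base
# comparison with the N rule.
oracle_scan <- function(primer, seqstr, strand = "+") {
  if (strand == "-") seqstr <- oracle_revcomp(seqstr)
  p <- strsplit(primer, "")[[1]]
  s <- strsplit(seqstr, "")[[1]]
  np <- length(p)
  best_mm <- Inf; best_off <- NA
  for (o in 0:(length(s) - np)) {
    w <- s[(o + 1):(o + np)]
    mm <- sum(p != w | p == "N" | w == "N")
    if (mm < best_mm) { best_mm <- mm; best_off <- o }
  }
  list(best_offset = best_off, mismatches = best_mm)
}

# Exhaustive peak-calling oracle on a single numeric coverage vector:
# enumerate maximal runs >= min_height, merge runs separated by < merge_gap,
# drop merged runs shorter than min_width. 0-based half-open output.
oracle_call_peaks <- function(cov, min_height, merge_gap, min_width) {
  above <- cov >= min_height
  runs <- list()
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i - 1, j)   # 0-based half-open
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(data.frame(start = integer(), end = integer()))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    gap <- r[1] - last[2]
    if (gap < merge_gap) merged[[length(merged)]] <- c(last[1], r[2])
    else merged[[length(merged) + 1]] <- r
  }
  out <- do.call(rbind, merged)
  out <- data.frame(start = out[, 1], end = out[, 2])
  out[out$end - out$start >= min_width, , drop = FALSE]
}

# Per-base replicate-depth consensus oracle.
oracle_consensus <- function(peaksets, L, min_replicates) {
  depth <- rep(0L, L)
  for (p in peaksets) {
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(p)))
      covered[(p$start[i] + 1):p$end[i]] <- TRUE
    depth <- depth + covered
  }
  above <- depth >= min_replicates
  runs <- list(); i <- 1
  while (i <= L) {
    if (above[i]) {
      j <- i
      while (j < L && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <-
        data.frame(start = i - 1, end = j,
                   support = max(depth[i:j]))
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs))
    return(data.frame(start = integer(), end = integer(),
                      support = integer()))
  do.call(rbind, runs)
}

# Exhaustive hypergeometric upper tail by enumerating all draws of n from N.
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# Random non-overlapping peak set on [0, L) for consensus tests.
random_peakset <- function(L, n_peaks) {
  if (n_peaks == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  cuts <- sort(sample(0:(L - 1), 2 * n_peaks))
  starts <- cuts[seq(1, 2 * n_peaks, 2)]
  ends <- cuts[seq(2, 2 * n_peaks, 2)]
  keep <- ends > starts
  data.frame(chrom = "chr1", start = starts[keep], end = ends[keep],
             strand = ".", stringsAsFactors = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
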