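#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a 2 Mb genome on
#' 2 chromosomes carrying 300 MaLR LTR instances over six families
#' (THE1A-D, MSTA, MSTB), 240 genes, three tumour-like and two control-like
#' samples with disjoint activation pools (tumour: 20% of loci active, 60%
#' shared core; control: ~6.7% active, 60% shared), three RACE replicates per
#' sample with a 0.45 per-locus capture dropout, 200 reads per captured locus
#' and 2000 uniform background reads per replicate, and a 4-fold expression
#' boost on genes driven by an active LTR.
#'
#' Each family consensus is a random 350 bp sequence sharing an embedded
#' 82 bp conserved 5' region; the 25 nt primer is the core of that region,
#' planted with family-specific fixed substitutions (THE1B 0, THE1A 1,
#' THE1C 2, THE1D 3, MSTA 5, MSTB 6) before per-copy divergence at
#' \code{divergence_rate}. This reproduces the THE1B amplification bias
#' mechanically: low-mismatch families amplify, high-mismatch families
#' frequently exceed the 8-mismatch budget.
#'
#' @param genome_length total genome size in bases.
#' @param n_chroms number of chromosomes (equal split).
#' @param family_proportions named fractions over the six families; must sum
#'   to 1.
#' @param n_repeats number of planted LTR instances.
#' @param divergence_rate per-base substitution probability from the family
#'   consensus.
#' @param n_genes number of gene models; must cover the genes required by the
#'   planted transcript-type cassettes.
#' @param activation per-group list with \code{active_fraction} and
#'   \code{shared_fraction}.
#' @param samples named list of sample ids per group (\code{tumour},
#'   \code{control}).
#' @param n_replicates RACE replicates per sample.
#' @param replicate_dropout probability an active locus yields no reads in a
#'   given replicate.
#' @param reads_per_active_ltr reads emitted per captured locus per replicate.
#' @param background_reads uniform background reads per replicate.
#' @param fragment_length RACE fragment length in bases.
#' @param max_mismatches primer mismatch budget.
#' @param ltr_expression_boost multiplicative FPKM effect on a gene driven by
#'   an active LTR.
#' @param primer optional explicit primer string; by default derived from the
#'   generated conserved region.
#' @param primer_length primer length when derived.
#' @param consensus_length family consensus length.
#' @param conserved_offset,conserved_length position/length of the embedded
#'   conserved region within the consensus.
#' @param primer_offset offset of the primer within the consensus.
#' @param planted_mismatches named integer vector of fixed primer-window
#'   substitutions per family.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline FPKM
#'   parameters (natural log scale).
#' @param noise_log_sd per-cell multiplicative log-normal noise (natural log
#'   sd).
#' @param ltr_cov_height coverage depth of a simulated LTR-initiated
#'   transcript.
#' @param lnc_transcript_length length of the transcript emitted by an
#'   intergenic lncRNA-type locus.
#' @param seed root random seed; every generator output is byte-identical
#'   under a fixed seed.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chroms = 2,
                       family_proportions = c(THE1A = 0.15, THE1B = 0.25,
                                              THE1C = 0.15, THE1D = 0.15,
                                              MSTA = 0.15, MSTB = 0.15),
                       n_repeats = 300,
                       divergence_rate = 0.15,
                       n_genes = 240,
                       activation = list(
                         tumour = list(active_fraction = 0.2,
                                       shared_fraction = 0.6),
                         control = list(active_fraction = 20 / 300,
                                        shared_fraction = 0.6)),
                       samples = list(
                         tumour = c("L428", "L1236", "KMH2"),
                         control = c("Reh", "Namalwa")),
                       n_replicates = 3,
                       replicate_dropout = 0.45,
                       reads_per_active_ltr = 200,
                       background_reads = 2000,
                       fragment_length = 150,
                       max_mismatches = 8,
                       ltr_expression_boost = 4,
                       primer = NULL,
                       primer_length = 25,
                       consensus_length = 350,
                       conserved_offset = 20,
                       conserved_length = 82,
                       primer_offset = 36,
                       planted_mismatches = c(THE1A = 1, THE1B = 0,
                                              THE1C = 2, THE1D = 3,
                                              MSTA = 5, MSTB = 6),
                       baseline_log_mean = log(10),
                       baseline_log_sd = 1.0,
                       noise_log_sd = 0.2,
                       ltr_cov_height = 10,
                       lnc_transcript_length = 2000,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a \code{sim_config} list.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (abs(sum(family_proportions) - 1) > 1e-9)
      stop("family_proportions must sum to 1")
    probs <- c(divergence_rate, replicate_dropout,
               vapply(activation, function(a)
                 c(a$active_fraction, a$shared_fraction), numeric(2)))
    if (any(probs < 0 | probs > 1))
      stop("all probabilities must be in [0, 1]")
    if (n_chroms < 1 || genome_length < n_chroms)
      stop("invalid genome geometry")
    if (primer_offset < conserved_offset ||
        primer_offset + primer_length > conserved_offset + conserved_length)
      stop("primer must lie within the conserved region")
    if (!setequal(names(planted_mismatches), names(family_proportions)))
      stop("planted_mismatches must cover the same families")
    if (seed < 0 || seed >= 2^31 || seed != trunc(seed))
      stop("seed must be a non-negative 32-bit integer")
  })
  invisible(config)
}

# One root seed, per-stage derived seeds (stage name hashed), so adding a
# stage never perturbs earlier stages. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2048993
  as.integer((seed * 1009 + h * 7919 + 1) %% 2147483647)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute bases at the given 1-based positions with a different base.
.substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- sample(alt, 1)
  }
  paste(ch, collapse = "")
}

# i.i.d. divergence: each base substituted with prob rate.
.diverge <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Cassette layouts, local coordinates on the cassette's own strand.
# Mirrored wholesale for '-' cassettes, so "downstream" is always correct in
# transcription orientation. Every gene's promoter window (1 kb upstream of
# the TSS) is contained within its own cassette, so windows never reach a
# neighbouring cassette's repeat; the upstream-promoter repeat sits 1.2 kb
# before its gene's TSS, outside the window. Widths are fixed so capacity is
# predictable.
.cassette_spec <- function(type, cfg) {
  rl <- cfg$consensus_length
  switch(type,
    upstream_promoter = list(width = 4650L,
      repeat_at = c(0L, rl), gene_at = c(1550L, 3550L), gene_sense = TRUE),
    intragenic_isoform = list(width = 4200L,
      repeat_at = c(1900L, 1900L + rl), gene_at = c(1100L, 3100L),
      gene_sense = TRUE),
    antisense = list(width = 4650L,
      repeat_at = c(0L, rl), gene_at = c(1550L, 3550L), gene_sense = FALSE),
    intergenic_lncRNA = list(width = 10350L,
      repeat_at = c(0L, rl), gene_at = NULL, gene_sense = NA),
    gene_only = list(width = 4200L,
      repeat_at = NULL, gene_at = c(1100L, 3100L), gene_sense = TRUE))
}

.mirror <- function(iv, w) c(w - iv[2], w - iv[1])

#' Build the synthetic genome
#'
#' Places non-overlapping LTR instances and gene models in planted
#' "cassettes" that realise the four LTR transcript types (intergenic
#' upstream promoter, intragenic isoform, antisense, intergenic lncRNA) in
#' equal rotation, embeds each instance as a diverged copy of its family
#' consensus, and records per-instance ground truth (planted transcript type,
#' primer-window mismatch count, associated gene).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genome} (named chromosome strings),
#'   \code{repeats} (interval frame with \code{instance_id}, \code{family},
#'   \code{repeat_class}, \code{planted_type}, \code{planted_mismatches},
#'   \code{assoc_gene}, \code{target_gene}), \code{genes} (interval frame
#'   with \code{gene_id}, \code{tss}; exon list in attribute \code{"exons"}),
#'   \code{primer}, \code{conserved_region}, \code{consensus} (per-family
#'   strings), \code{config}.
#' @export
build_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  fams <- names(config$family_proportions)

  conserved <- .random_dna(config$conserved_length)
  primer <- if (!is.null(config$primer)) config$primer else
    substr(conserved,
           config$primer_offset - config$conserved_offset + 1L,
           config$primer_offset - config$conserved_offset +
             config$primer_length)
  pw0 <- config$primer_offset            # primer window start in consensus
  pl <- config$primer_length

  consensus <- list()
  for (f in fams) {
    base <- .random_dna(config$consensus_length)
    substr(base, config$conserved_offset + 1L,
           config$conserved_offset + config$conserved_length) <- conserved
    k <- config$planted_mismatches[[f]]
    if (k > 0) {
      pos <- sample(seq(pw0 + 1L, pw0 + pl), k)
      base <- .substitute_at(base, pos)
    }
    consensus[[f]] <- base
  }

  # family composition: counts from proportions, largest-remainder rounding
  n_rep <- config$n_repeats
  raw <- config$family_proportions * n_rep
  cnt <- floor(raw)
  left <- n_rep - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  fam_of <- sample(rep(fams, times = cnt))

  types <- c("upstream_promoter", "intragenic_isoform", "antisense",
             "intergenic_lncRNA")
  type_of <- if (n_rep > 0) rep_len(types, n_rep) else character()
  n_cassette_genes <- sum(type_of != "intergenic_lncRNA")
  if (config$n_genes < n_cassette_genes)
    stop("capacity error: n_genes (", config$n_genes,
         ") below the ", n_cassette_genes, " genes required by cassettes")
  n_extra_genes <- config$n_genes - n_cassette_genes

  chrom_len <- rep(floor(config$genome_length / config$n_chroms),
                   config$n_chroms)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  cursors <- rep(0L, config$n_chroms)
  cur_chrom <- 1L

  plan <- c(type_of, rep("gene_only", n_extra_genes))
  rep_rows <- vector("list", n_rep)
  gene_rows <- list()
  exons <- list()
  edits <- vector("list", length(plan))   # sequence patches per cassette
  ri <- 0L; gi <- 0L

  for (ci in seq_along(plan)) {
    type <- plan[ci]
    spec <- .cassette_spec(type, config)
    w <- spec$width
    gap <- as.integer(floor(stats::runif(1, 0, 500)))
    cs <- sample(c("+", "-"), 1)
    repeat {
      if (cursors[cur_chrom] + gap + w <= chrom_len[cur_chrom]) break
      cur_chrom <- cur_chrom + 1L
      if (cur_chrom > config$n_chroms)
        stop("capacity error: genome too small for requested features")
    }
    off <- cursors[cur_chrom] + gap
    cursors[cur_chrom] <- off + w
    chrom <- chrom_names[cur_chrom]
    place <- function(iv) {
      if (cs == "-") iv <- .mirror(iv, w)
      c(off + iv[1], off + iv[2])
    }

    gene_id <- NA_character_
    if (!is.null(spec$gene_at)) {
      gi <- gi + 1L
      gene_id <- sprintf("gene%03d", gi)
      giv <- place(spec$gene_at)
      gs <- if (isTRUE(spec$gene_sense)) cs else c("+" = "-", "-" = "+")[[cs]]
      gene_rows[[gi]] <- data.frame(chrom = chrom, start = giv[1],
                                    end = giv[2], strand = gs,
                                    gene_id = gene_id,
                                    stringsAsFactors = FALSE)
      exons[[gene_id]] <- gintervals(
        chrom = c(chrom, chrom),
        start = c(giv[1], giv[2] - 400L),
        end = c(giv[1] + 400L, giv[2]),
        strand = gs)
    }

    if (!is.null(spec$repeat_at)) {
      ri <- ri + 1L
      fam <- fam_of[ri]
      inst <- .diverge(consensus[[fam]], config$divergence_rate)
      pm <- count_mismatches(primer, substr(inst, pw0 + 1L, pw0 + pl))
      riv <- place(spec$repeat_at)
      rep_rows[[ri]] <- data.frame(
        chrom = chrom, start = riv[1], end = riv[2], strand = cs,
        instance_id = sprintf("LTR_%03d", ri), family = fam,
        repeat_class = "LTR/MaLR", planted_type = type,
        planted_mismatches = pm,
        assoc_gene = if (type %in% c("upstream_promoter",
                                     "intragenic_isoform"))
          gene_id else NA_character_,
        target_gene = if (type %in% c("upstream_promoter",
                                      "intragenic_isoform", "antisense"))
          gene_id else NA_character_,
        stringsAsFactors = FALSE)
      gseq <- if (cs == "-") revcomp(inst) else inst
      edits[[ci]] <- list(chrom = chrom, start = riv[1], seq = gseq)
    }
  }

  genome <- vapply(chrom_len, .random_dna, character(1))
  names(genome) <- chrom_names
  for (e in edits) {
    if (is.null(e)) next
    substr(genome[[e$chrom]], e$start + 1L,
           e$start + nchar(e$seq)) <- e$seq
  }

  repeats <- if (ri > 0) do.call(rbind, rep_rows[seq_len(ri)]) else
    gintervals(instance_id = character(), family = character(),
               repeat_class = character(), planted_type = character(),
               planted_mismatches = integer(), assoc_gene = character(),
               target_gene = character())
  genes <- if (gi > 0) do.call(rbind, gene_rows) else
    gintervals(gene_id = character())
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  attr(genes, "exons") <- exons
  rownames(repeats) <- NULL; rownames(genes) <- NULL

  list(genome = genome, repeats = repeats, genes = genes,
       primer = primer, conserved_region = conserved,
       consensus = consensus, config = config)
}

#' Genome chromosome lengths
#' @param genome named character vector of chromosome sequences.
#' @return named integer vector.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

#' Assign per-sample binary activation states
#'
#' Tumour-like samples share a core active set (a \code{shared_fraction} of
#' each sample's active count) plus sample-private loci; control-like samples
#' draw from a disjoint pool with the same structure. The two pools partition
#' the loci, so tumour and control active sets never intersect.
#'
#' @param repeats repeat interval frame (\code{instance_id}).
#' @param sample_groups named list (\code{tumour}, \code{control}) of sample
#'   ids.
#' @param config a \code{\link{sim_config}}.
#' @param seed root seed (defaults to \code{config$seed}).
#' @return binary matrix, rows = instance ids, columns = samples.
#' @export
assign_activation <- function(repeats, sample_groups, config,
                              seed = config$seed) {
  validate_sim_config(config)
  set.seed(derive_seed(seed, "activation"))
  loci <- repeats$instance_id
  n <- length(loci)
  samples <- unlist(sample_groups, use.names = FALSE)
  mat <- matrix(0L, nrow = n, ncol = length(samples),
                dimnames = list(loci, samples))
  perm <- sample(loci)
  half <- floor(n / 2)
  pools <- list(tumour = perm[seq_len(half)],
                control = perm[setdiff(seq_len(n), seq_len(half))])
  for (grp in names(sample_groups)) {
    act <- config$activation[[grp]]
    pool <- pools[[grp]]
    n_active <- round(act$active_fraction * n)
    n_core <- round(act$shared_fraction * n_active)
    n_priv <- n_active - n_core
    if (n_active > length(pool))
      stop("capacity error: requested active count exceeds pool for ", grp)
    core <- if (n_core > 0) sample(pool, n_core) else character()
    rest <- setdiff(pool, core)
    for (s in sample_groups[[grp]]) {
      priv <- if (n_priv > 0) sample(rest, n_priv) else character()
      mat[c(core, priv), s] <- 1L
    }
  }
  mat
}

#' Simulate RACE-Seq read intervals with replicate dropout
#'
#' A locus yields reads in a replicate iff it is active in that sample, its
#' best ungapped primer match is within the mismatch budget, and a
#' Bernoulli(1 - replicate_dropout) capture draw succeeds. Captured loci emit
#' \code{reads_per_active_ltr} identical fragments starting at the primer
#' match position on the repeat strand; \code{background_reads} fragments are
#' placed uniformly per replicate.
#'
#' @param genome named chromosome strings.
#' @param repeats repeat interval frame.
#' @param activation binary matrix from \code{\link{assign_activation}}.
#' @param primer primer string.
#' @param config a \code{\link{sim_config}}.
#' @param seed root seed (defaults to \code{config$seed}).
#' @return list with \code{reads} (per sample, per replicate interval
#'   frames), \code{captured} (locus x sample x replicate logical array),
#'   \code{scan} (per-instance primer scan results from
#'   \code{\link{amplifiable_set}}).
#' @export
simulate_race_reads <- function(genome, repeats, activation, primer, config,
                                seed = config$seed) {
  validate_sim_config(config)
  scan <- amplifiable_set(primer, repeats, genome, config$max_mismatches)
  amp <- scan$amplifiable
  fl <- config$fragment_length
  # genomic interval of each captured read: primer match position, extending
  # in transcription orientation
  rd_start <- ifelse(repeats$strand == "-",
                     repeats$end - scan$best_offset - fl,
                     repeats$start + scan$best_offset)
  rd_start <- pmax(rd_start, 0L)
  glen <- genome_lengths(genome)
  set.seed(derive_seed(seed, "race_reads"))
  samples <- colnames(activation)
  n_loci <- nrow(repeats)
  captured <- array(FALSE,
                    dim = c(n_loci, length(samples), config$n_replicates),
                    dimnames = list(repeats$instance_id, samples,
                                    paste0("rep", seq_len(config$n_replicates))))
  reads <- list()
  for (s in samples) {
    reads[[s]] <- list()
    for (r in seq_len(config$n_replicates)) {
      keep <- activation[, s] == 1L & amp &
        stats::runif(n_loci) >= config$replicate_dropout
      captured[, s, r] <- keep
      idx <- rep(which(keep), each = config$reads_per_active_ltr)
      sig <- if (length(idx))
        data.frame(chrom = repeats$chrom[idx],
                   start = rd_start[idx],
                   end = rd_start[idx] + fl,
                   strand = repeats$strand[idx],
                   stringsAsFactors = FALSE)
      else gintervals()
      nb <- config$background_reads
      if (nb > 0) {
        bchrom <- sample(names(glen), nb, replace = TRUE,
                         prob = glen / sum(glen))
        bstart <- floor(stats::runif(nb, 0, glen[bchrom] - fl))
        bg <- data.frame(chrom = bchrom, start = as.integer(bstart),
                         end = as.integer(bstart) + fl,
                         strand = sample(c("+", "-"), nb, replace = TRUE),
                         stringsAsFactors = FALSE)
        sig <- rbind(sig, bg)
      }
      rownames(sig) <- NULL
      reads[[s]][[paste0("rep", r)]] <- sig
    }
  }
  list(reads = reads, captured = captured, scan = scan)
}

#' Simulate expression tables and stranded coverage
#'
#' Baseline FPKM is log-normal per gene; a gene associated to an LTR active
#' in a sample has its FPKM multiplied by \code{ltr_expression_boost} in that
#' sample. Coverage tracks carry exonic baseline signal on the gene strand
#' plus, for each active locus, an LTR-initiated transcript on the LTR strand
#' running from the LTR 5' end through the associated/overlapped gene body
#' (transcript types 1-3) or for \code{lnc_transcript_length} bases
#' (type 4).
#'
#' @param genes gene interval frame (exons in attribute \code{"exons"}).
#' @param repeats repeat interval frame with planted-truth columns.
#' @param activation binary activation matrix.
#' @param config a \code{\link{sim_config}}.
#' @param seed root seed (defaults to \code{config$seed}).
#' @param chrom_lengths named chromosome lengths (required for dense tracks).
#' @return list with \code{fpkm} (gene x sample matrix) and \code{coverage}
#'   (per sample: list of \code{plus}/\code{minus} \code{RleList} tracks).
#' @export
simulate_expression <- function(genes, repeats, activation, config,
                                seed = config$seed,
                                chrom_lengths = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(seed, "expression"))
  samples <- colnames(activation)
  ng <- nrow(genes)
  baseline <- exp(stats::rnorm(ng, config$baseline_log_mean,
                               config$baseline_log_sd))
  names(baseline) <- genes$gene_id
  noise <- matrix(exp(stats::rnorm(ng * length(samples), 0,
                                   config$noise_log_sd)),
                  nrow = ng,
                  dimnames = list(genes$gene_id, samples))
  boosted <- matrix(FALSE, nrow = ng, ncol = length(samples),
                    dimnames = list(genes$gene_id, samples))
  has_assoc <- which(!is.na(repeats$assoc_gene))
  for (i in has_assoc) {
    g <- repeats$assoc_gene[i]
    on <- activation[repeats$instance_id[i], ] == 1L
    boosted[g, on] <- TRUE
  }
  fpkm <- baseline * noise *
    ifelse(boosted, config$ltr_expression_boost, 1)

  if (is.null(chrom_lengths))
    stop("chrom_lengths required to build coverage tracks")
  exons <- attr(genes, "exons")
  gene_row <- stats::setNames(seq_len(ng), genes$gene_id)
  coverage <- list()
  for (s in samples) {
    segs <- list(); k <- 0L
    add <- function(chrom, start, end, strand, h) {
      k <<- k + 1L
      segs[[k]] <<- data.frame(chrom = chrom, start = start, end = end,
                               strand = strand, h = h,
                               stringsAsFactors = FALSE)
    }
    for (g in seq_len(ng)) {
      ex <- exons[[genes$gene_id[g]]]
      if (is.null(ex) || !nrow(ex)) next
      add(ex$chrom, ex$start, ex$end, ex$strand,
          rep(fpkm[g, s] / 10, nrow(ex)))
    }
    for (i in which(activation[, s] == 1L)) {
      type <- repeats$planted_type[i]
      tg <- repeats$target_gene[i]
      if (!is.na(tg)) {
        grow <- gene_row[[tg]]
        span <- if (repeats$strand[i] == "+")
          c(repeats$start[i], max(repeats$end[i], genes$end[grow]))
        else
          c(min(repeats$start[i], genes$start[grow]), repeats$end[i])
      } else {
        span <- if (repeats$strand[i] == "+")
          c(repeats$start[i],
            min(repeats$start[i] + config$lnc_transcript_length,
                chrom_lengths[[repeats$chrom[i]]]))
        else
          c(max(repeats$end[i] - config$lnc_transcript_length, 0),
            repeats$end[i])
      }
      add(repeats$chrom[i], span[1], span[2], repeats$strand[i],
          config$ltr_cov_height)
    }
    seg <- if (k > 0) do.call(rbind, segs) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), h = numeric())
    coverage[[s]] <- list(
      plus = .weighted_coverage(seg[seg$strand == "+", ], chrom_lengths),
      minus = .weighted_coverage(seg[seg$strand == "-", ], chrom_lengths))
  }
  list(fpkm = fpkm, coverage = coverage)
}

.weighted_coverage <- function(seg, chrom_lengths) {
  if (!nrow(seg)) {
    return(do.call(IRanges::RleList, stats::setNames(
      lapply(chrom_lengths, function(L) S4Vectors::Rle(0, L)),
      names(chrom_lengths))))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(seg$chrom, levels = names(chrom_lengths)),
    ranges = IRanges::IRanges(start = seg$start + 1L, end = seg$end),
    seqlengths = chrom_lengths)
  GenomicRanges::coverage(gr, weight = seg$h)
}

#' Run the full generator under one configuration
#'
#' Convenience wrapper: genome + activation + RACE reads + expression.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed root seed (defaults to \code{config$seed}).
#' @return list with all generator outputs (\code{genome}, \code{repeats},
#'   \code{genes}, \code{primer}, \code{activation}, \code{race},
#'   \code{expression}, \code{config}).
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  gen <- build_genome(config)
  act <- assign_activation(gen$repeats, config$samples, config, seed)
  race <- simulate_race_reads(gen$genome, gen$repeats, act, gen$primer,
                              config, seed)
  expr <- simulate_expression(gen$genes, gen$repeats, act, config, seed,
                              chrom_lengths = genome_lengths(gen$genome))
  c(gen, list(activation = act, race = race, expression = expr))
}
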