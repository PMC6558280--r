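#' Read a BED file
#'
#' BED3/BED6 reader preserving the native 0-based half-open coordinates.
#' Optional columns 4 (name), 5 (score) and 6 (strand) are kept when present
#' so that \code{\link{write_bed}} round-trips well-formed input
#' byte-identically.
#'
#' @param path path to a tab-separated BED file.
#' @return interval data.frame (see \code{\link{gintervals}}); extra columns
#'   \code{name}/\code{score} when the file has them. The number of fields
#'   seen is stored in attribute \code{"n_fields"}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- gintervals()
    attr(out, "n_fields") <- 3L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  nf_use <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(nf_use)], character(nf_use)))
  start <- suppressWarnings(as.integer(mat[, 2]))
  end <- suppressWarnings(as.integer(mat[, 3]))
  if (any(is.na(start)) || any(is.na(end))) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("malformed BED line ", bad, ": non-numeric coordinate")
  }
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid BED line ", bad[1], ": start >= end")
  if (any(start < 0))
    stop("invalid BED line ", which(start < 0)[1], ": negative start")
  strand <- if (nf_use >= 6) mat[, 6] else "."
  if (!all(strand %in% c("+", "-", ".")))
    stop("invalid BED strand value; must be '+', '-' or '.'")
  out <- data.frame(chrom = mat[, 1], start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  if (nf_use >= 4) out$name <- mat[, 4]
  if (nf_use >= 5) out$score <- mat[, 5]
  attr(out, "n_fields") <- as.integer(nf_use)
  out
}

#' Write intervals as BED
#'
#' Emits BED3 when no name/score/strand information is present, BED6
#' otherwise (name \code{"."}, score \code{0} where missing).
#'
#' @param x interval data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_gintervals(x, "write_bed")
  nf <- attr(x, "n_fields")
  has6 <- ("name" %in% names(x)) || ("score" %in% names(x)) ||
    any(x$strand != ".") || (!is.null(nf) && nf >= 6)
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (!has6) {
    lines <- paste(x$chrom, x$start, x$end, sep = "\t")
  } else {
    name <- if ("name" %in% names(x)) x$name else "."
    score <- if ("score" %in% names(x)) x$score else 0
    lines <- paste(x$chrom, x$start, x$end, name, score, x$strand, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a RepeatMasker .out annotation
#'
#' Parses the standard RepeatMasker \code{.out} dialect (3 header lines, then
#' whitespace-delimited records). The 1-based inclusive coordinates are
#' converted to 0-based half-open; strand \code{"C"} (complement) becomes
#' \code{"-"}. The repeat name column provides \code{family}, the
#' class/family column \code{repeat_class}.
#'
#' @param path path to a RepeatMasker .out file.
#' @return interval data.frame with columns \code{family},
#'   \code{repeat_class}, \code{instance_id}.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker file not found: ", path)
  lines <- readLines(path)
  if (length(lines) >= 3) lines <- lines[-(1:3)] else lines <- character()
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(gintervals(family = character(), repeat_class = character(),
                      instance_id = character()))
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("RepeatMasker record ", which(nf < 11)[1],
         " has fewer than 11 columns")
  get <- function(i) vapply(fields, `[[`, character(1), i)
  begin <- suppressWarnings(as.integer(get(6)))
  end <- suppressWarnings(as.integer(get(7)))
  if (any(is.na(begin)) || any(is.na(end)))
    stop("RepeatMasker record ", which(is.na(begin) | is.na(end))[1],
         ": non-numeric coordinates")
  strand_raw <- get(9)
  if (!all(strand_raw %in% c("+", "C")))
    stop("RepeatMasker strand column must be '+' or 'C'")
  ids <- if (all(nf >= 15)) get(15) else as.character(seq_along(lines))
  out <- gintervals(chrom = get(5), start = begin - 1L, end = end,
                    strand = ifelse(strand_raw == "C", "-", "+"),
                    family = get(10), repeat_class = get(11),
                    instance_id = ids)
  if (anyDuplicated(out$instance_id))
    out$instance_id <- paste0(out$instance_id, "_", seq_len(nrow(out)))
  out
}

#' Write repeats in a RepeatMasker-style .out layout
#'
#' Mirrors the column order expected by \code{\link{read_repeatmasker_out}};
#' placeholder values are used for alignment statistics that the synthetic
#' annotation does not model.
#'
#' @param repeats interval data.frame with \code{family}, \code{repeat_class},
#'   \code{instance_id} columns.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  validate_gintervals(repeats, "write_repeatmasker_out")
  hdr <- c(
    "   SW   perc perc perc  query     position in query  matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end   (left) repeat    class/family  begin end (left) ID",
    "")
  if (nrow(repeats)) {
    rec <- sprintf("%5d %6.1f %4.1f %4.1f  %s %d %d (0) %s %s %s %d %d (0) %s",
                   1000L, 15.0, 0.0, 0.0,
                   repeats$chrom, repeats$start + 1L, repeats$end,
                   ifelse(repeats$strand == "-", "C", "+"),
                   repeats$family, repeats$repeat_class,
                   1L, repeats$end - repeats$start,
                   repeats$instance_id)
  } else rec <- character()
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a gene annotation
#'
#' Accepts either a minimal 5-column TSV (\code{gene_id, chrom, start, end,
#' strand}; header optional, coordinates 0-based half-open) or BED12 (blocks
#' become exons). The TSS is derived from the strand: interval start for
#' \code{"+"} genes, \code{end - 1} for \code{"-"} genes.
#'
#' @param path input path.
#' @param format \code{"tsv"} or \code{"bed12"}.
#' @return interval data.frame with columns \code{gene_id}, \code{tss} and an
#'   attribute \code{"exons"} (named list of interval frames, possibly empty).
#' @export
read_genes <- function(path, format = c("tsv", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene annotation not found: ", path)
  if (format == "tsv") {
    first <- readLines(path, n = 1)
    has_header <- grepl("gene_id", first, fixed = TRUE)
    df <- utils::read.delim(path, header = has_header,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 5) stop("gene TSV needs 5 columns")
    names(df)[1:5] <- c("gene_id", "chrom", "start", "end", "strand")
    genes <- gintervals(chrom = df$chrom, start = df$start, end = df$end,
                        strand = df$strand, gene_id = as.character(df$gene_id))
    attr(genes, "exons") <- list()
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 12))
      stop("BED12 line ", which(lengths(fields) < 12)[1],
           " has fewer than 12 fields")
    mat <- t(vapply(fields, `[`, character(12), 1:12))
    start <- as.integer(mat[, 2]); end <- as.integer(mat[, 3])
    genes <- gintervals(chrom = mat[, 1], start = start, end = end,
                        strand = mat[, 6], gene_id = mat[, 4])
    exons <- vector("list", nrow(genes))
    names(exons) <- genes$gene_id
    for (i in seq_len(nrow(genes))) {
      sizes <- as.integer(strsplit(mat[i, 11], ",")[[1]])
      offs <- as.integer(strsplit(mat[i, 12], ",")[[1]])
      exons[[i]] <- gintervals(chrom = rep(mat[i, 1], length(sizes)),
                               start = start[i] + offs,
                               end = start[i] + offs + sizes,
                               strand = mat[i, 6])
    }
    attr(genes, "exons") <- exons
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes
}

#' Write genes as the minimal 5-column TSV
#' @param genes gene interval data.frame with \code{gene_id}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genes_tsv <- function(genes, path) {
  utils::write.table(
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$start, end = genes$end, strand = genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression table
#'
#' TSV with a header row; first column gene identifiers, remaining columns
#' numeric per-sample values (FPKM in this pipeline). Duplicate gene ids and
#' non-numeric or missing cells are rejected; negative values are accepted
#' with a warning (log-scale input is possible upstream).
#'
#' @param path input path.
#' @return numeric matrix, rownames = gene ids, colnames = sample ids.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2) stop("expression table needs gene_id plus >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene_id in expression table: ",
         ids[duplicated(ids)][1])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop("non-numeric expression value in column ", names(vals)[j])
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  if (any(is.na(m))) stop("missing values in expression table")
  if (any(m < 0))
    warning("negative expression values present; treating input as-is ",
            "(log-scale input possible)")
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#' @param mat numeric matrix with gene rownames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#' @param cov an \code{RleList} of per-base signal, one element per chromosome.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(cov, path) {
  gr <- GenomicRanges::bindAsGRanges(score = methods::as(cov, "RleList"))
  gr <- gr[S4Vectors::mcols(gr)$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a dense coverage track
#' @param path bedGraph path.
#' @param genome_lengths named integer vector of chromosome lengths.
#' @return an \code{RleList} covering every chromosome end-to-end.
#' @export
read_bedgraph <- function(path, genome_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- names(genome_lengths)
  GenomeInfoDb::seqlengths(gr) <- genome_lengths
  GenomicRanges::coverage(gr, weight = "score")
}
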