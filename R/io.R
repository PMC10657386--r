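# Readers/writers for the standard formats the simulator touches
# (FASTA, FASTQ, SAM, BED, GTF, MTX) plus strand-aware sequence extraction.
#
# In-memory conventions:
#   * a reference genome is a named Biostrings::DNAStringSet;
#   * single-end reads are a data.frame with columns
#       qname, chrom, pos5 (0-based 5'-most base), len, strand, cell, umi;
#   * read pairs are a data.frame with one row per pair:
#       qname, chrom, pos5_1, len1, strand_1, pos5_2, len2, strand_2,
#       cell, frag (outer fragment size in bp).

#' Load a reference genome from FASTA
#' @param path FASTA file.
#' @return named `DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Chromosome lengths of a genome
#' @param genome named `DNAStringSet`.
#' @return named integer vector chromosome -> length (bp).
#' @export
chrom_sizes <- function(genome) {
  stats::setNames(Biostrings::width(genome),
                  sub("\\s.*$", "", names(genome)))
}

#' Extract strand-aware sequences from a genome
#'
#' Plus-strand (or unstranded) intervals return the forward substring;
#' minus-strand intervals return its reverse complement.  Coordinates are
#' 0-based half-open.
#'
#' @param genome named `DNAStringSet`.
#' @param chrom,start,end,strand vectors describing the intervals.
#' @return character vector of uppercase sequences.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  n <- length(chrom)
  if (n == 0L) return(character())
  strand <- rep_len(strand, n)
  sizes <- chrom_sizes(genome)
  names(genome) <- names(sizes)
  unknown <- setdiff(unique(chrom), names(sizes))
  if (length(unknown)) stop("unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  if (any(start < 0L) || any(end > sizes[chrom]) || any(start >= end)) {
    stop("interval out of chromosome bounds")
  }
  out <- character(n)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    seqs <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(start = start[ix] + 1L, end = end[ix]))
    minus <- strand[ix] == "-"
    if (any(minus)) {
      seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    }
    out[ix] <- toupper(as.character(seqs))
  }
  out
}

#' Write sequencing records to a FASTQ file (Phred+33)
#'
#' @param records data.frame with columns `name`, `seq`, `qual` (quality as a
#'   Phred+33 character string of the same length as `seq`).
#' @param path output file.
#' @export
write_fastq <- function(records, path) {
  if (nrow(records) > 0L &&
      any(nchar(records$seq) != nchar(records$qual))) {
    stop("sequence/quality length mismatch")
  }
  if (nrow(records) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", records$name),
                           records$seq,
                           "+",
                           records$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ file.
#' @return data.frame with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(name = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  stopifnot(length(lines) %% 4L == 0L)
  ix <- seq(1L, length(lines), by = 4L)
  data.frame(name = sub("^@", "", lines[ix]),
             seq = lines[ix + 1L],
             qual = lines[ix + 3L],
             stringsAsFactors = FALSE)
}

# ---- SAM ----

.sam_header <- function(sizes) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(sizes), as.integer(sizes)))
}

.leftmost <- function(pos5, len, strand) {
  ifelse(strand == "-", pos5 - len + 1L, pos5)
}

#' Write aligned reads or read pairs as SAM
#'
#' Emits coordinate-sorted plain-text SAM with `CB` (cell barcode) and, for
#' UMI-tagged reads, `UB` tags.  Sequences are written when a `seq` column is
#' present, `*` otherwise.  Round-trips through [read_alignments()].
#'
#' @param reads single-end read data.frame, or `NULL`.
#' @param pairs read-pair data.frame, or `NULL`.
#' @param sizes named chromosome lengths.
#' @param path output `.sam` path.
#' @export
write_alignments <- function(path, sizes, reads = NULL, pairs = NULL) {
  recs <- character()
  fmt_tags <- function(cell, umi) {
    tg <- sprintf("CB:Z:%s", cell)
    if (!is.null(umi) && !all(is.na(umi))) {
      tg <- paste0(tg, sprintf("\tUB:Z:%s", umi))
    }
    tg
  }
  if (!is.null(reads) && nrow(reads) > 0L) {
    if (any(!reads$chrom %in% names(sizes))) stop("unknown chromosome")
    left <- .leftmost(reads$pos5, reads$len, reads$strand)
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    seq <- if ("seq" %in% names(reads)) reads$seq else "*"
    qual <- if ("qual" %in% names(reads)) reads$qual else "*"
    recs <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\t%s",
                    reads$qname, flag, reads$chrom, left + 1L, reads$len,
                    seq, qual, fmt_tags(reads$cell, reads$umi))
    ord <- order(reads$chrom, left)
    recs <- recs[ord]
  }
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    if (any(!pairs$chrom %in% names(sizes))) stop("unknown chromosome")
    l1 <- .leftmost(pairs$pos5_1, pairs$len1, pairs$strand_1)
    l2 <- .leftmost(pairs$pos5_2, pairs$len2, pairs$strand_2)
    base1 <- 1L + 2L + 64L +
      ifelse(pairs$strand_1 == "-", 16L, 0L) +
      ifelse(pairs$strand_2 == "-", 32L, 0L)
    base2 <- 1L + 2L + 128L +
      ifelse(pairs$strand_2 == "-", 16L, 0L) +
      ifelse(pairs$strand_1 == "-", 32L, 0L)
    tlen <- pmax(l1 + pairs$len1, l2 + pairs$len2) - pmin(l1, l2)
    s1 <- if ("seq1" %in% names(pairs)) pairs$seq1 else "*"
    s2 <- if ("seq2" %in% names(pairs)) pairs$seq2 else "*"
    tags <- fmt_tags(pairs$cell, NULL)
    r1 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*\t%s",
                  pairs$qname, base1, pairs$chrom, l1 + 1L, pairs$len1,
                  l2 + 1L, ifelse(l1 <= l2, tlen, -tlen), s1, tags)
    r2 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*\t%s",
                  pairs$qname, base2, pairs$chrom, l2 + 1L, pairs$len2,
                  l1 + 1L, ifelse(l2 < l1, tlen, -tlen), s2, tags)
    both <- c(r1, r2)
    ord <- order(c(pairs$chrom, pairs$chrom), c(l1, l2))
    recs <- c(recs, both[ord])
  }
  writeLines(c(.sam_header(sizes), recs), path)
  invisible(path)
}

#' Read aligned reads from SAM/BAM
#'
#' Reads are parsed with Rsamtools (SAM files are converted to temporary BAM
#' first); unmapped, secondary, supplementary and duplicate-flagged records
#' are dropped by default.  Cell barcode and UMI are pulled from configurable
#' tags.  Reads missing the barcode tag are skipped with a warning summary.
#'
#' @param path SAM or BAM file.
#' @param cell_tag,umi_tag tag names (defaults `CB`, `UB`).
#' @param paired if `TRUE`, mate records sharing a read name are linked and
#'   returned as a pair table.
#' @return for `paired = FALSE`, a read data.frame (see file header);
#'   for `paired = TRUE`, a list with `pairs` and the underlying `reads`.
#' @export
read_alignments <- function(path, cell_tag = "CB", umi_tag = "UB",
                            paired = FALSE) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressWarnings(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "strand", "qwidth", "seq"),
    tag = unique(c(cell_tag, umi_tag)))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(res$qname)
  cell <- res$tag[[cell_tag]]
  umi <- res$tag[[umi_tag]]
  if (is.null(cell)) cell <- rep(NA_character_, n)
  if (is.null(umi)) umi <- rep(NA_character_, n)
  strand <- as.character(res$strand)
  pos5 <- ifelse(strand == "-",
                 res$pos - 1L + res$qwidth - 1L,
                 res$pos - 1L)
  reads <- data.frame(qname = res$qname, chrom = as.character(res$rname),
                      pos5 = as.integer(pos5), len = as.integer(res$qwidth),
                      strand = strand, cell = cell, umi = umi,
                      seq = as.character(res$seq),
                      first_mate = bitwAnd(res$flag, 64L) > 0L,
                      stringsAsFactors = FALSE)
  miss <- is.na(reads$cell)
  if (any(miss)) {
    warning(sum(miss), " read(s) missing tag ", cell_tag, "; skipped")
    reads <- reads[!miss, , drop = FALSE]
  }
  if (!paired) return(reads)
  list(pairs = link_mates(reads), reads = reads)
}

#' Link mate records sharing a read name into a pair table
#' @param reads read data.frame including a `first_mate` logical column.
#' @return pair data.frame (see file header); reads without exactly one mate
#'   are dropped.
#' @export
link_mates <- function(reads) {
  tb <- table(reads$qname)
  keep <- names(tb)[tb == 2L]
  reads <- reads[reads$qname %in% keep, , drop = FALSE]
  reads <- reads[order(reads$qname, !reads$first_mate), , drop = FALSE]
  i1 <- seq(1L, nrow(reads), by = 2L)
  i2 <- i1 + 1L
  m1 <- reads[i1, , drop = FALSE]
  m2 <- reads[i2, , drop = FALSE]
  pairs <- data.frame(qname = m1$qname, chrom = m1$chrom,
                      pos5_1 = m1$pos5, len1 = m1$len, strand_1 = m1$strand,
                      pos5_2 = m2$pos5, len2 = m2$len, strand_2 = m2$strand,
                      cell = m1$cell, stringsAsFactors = FALSE)
  pairs$frag <- fragment_size(pairs)
  pairs
}

#' Outer fragment size of read pairs
#' @param pairs pair data.frame.
#' @return integer vector of outer distances (bp).
#' @export
fragment_size <- function(pairs) {
  l1 <- .leftmost(pairs$pos5_1, pairs$len1, pairs$strand_1)
  l2 <- .leftmost(pairs$pos5_2, pairs$len2, pairs$strand_2)
  as.integer(pmax(l1 + pairs$len1, l2 + pairs$len2) - pmin(l1, l2))
}

# ---- BED ----

#' Write intervals to BED (0-based half-open)
#' @param df interval table.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  if (nrow(df) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("id" %in% names(df)) df$id else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, name),
             path)
  invisible(path)
}

#' Read a BED file into an interval table
#' @param path BED path.
#' @param label label to assign.
#' @return interval table.
#' @export
read_bed <- function(path, label = NA_character_) {
  if (length(readLines(path, n = 1L)) == 0L) return(.empty_intervals())
  gr <- rtracklayer::import(path, format = "BED")
  id <- if (!is.null(gr$name)) gr$name else NULL
  .gr2gi(gr, label = label, id = id)
}

# ---- GTF ----

#' Read gene and exon records from a GTF file
#'
#' Coordinates are converted from GTF's 1-based closed convention to the
#' internal 0-based half-open convention.
#'
#' @param path GTF file.
#' @return list with interval tables `genes` (id = gene_id) and `exons`
#'   (with `gene_id` column).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  g <- .gr2gi(genes, label = "gene", id = genes$gene_id)
  e <- .gr2gi(exons, label = "exon",
              id = sprintf("exon_%d", seq_along(exons)))
  # .gr2gi re-sorts by (chrom, start, end); carry gene_id along the same key
  eo <- order(as.character(GenomicRanges::seqnames(exons)),
              GenomicRanges::start(exons) - 1L, GenomicRanges::end(exons))
  e$gene_id <- exons$gene_id[eo]
  list(genes = g, exons = e)
}

#' Write a toy annotation (genes/transcripts/exons) to GTF
#' @param genes interval table of genes (id = gene id).
#' @param exons interval table of exons with `gene_id` and `transcript_id`.
#' @param path output path.
#' @export
write_gtf <- function(genes, exons, path) {
  fmt <- function(df, type, attr) {
    sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$chrom, type, df$start + 1L, df$end, df$strand, attr)
  }
  glines <- fmt(genes, "gene", sprintf("gene_id \"%s\";", genes$id))
  elines <- fmt(exons, "exon",
                sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                        exons$gene_id, exons$transcript_id))
  writeLines(c(glines, elines), path)
  invisible(path)
}

# ---- MTX ----

#' Write a feature-by-cell count matrix as MTX plus axis TSVs
#' @param mat `dgCMatrix`/matrix with dimnames (features, barcodes).
#' @param dir output directory (created if needed).
#' @export
write_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(mat, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a feature-by-cell matrix written by [write_matrix()]
#' @param dir directory with matrix.mtx, features.tsv, barcodes.tsv.
#' @return `dgCMatrix` with dimnames.
#' @export
read_matrix <- function(dir) {
  mat <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                     "CsparseMatrix")
  dimnames(mat) <- list(readLines(file.path(dir, "features.tsv")),
                        readLines(file.path(dir, "barcodes.tsv")))
  mat
}
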