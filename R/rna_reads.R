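# Synthetic scRNA-seq read generation.
#
# Read 2 (the cDNA-bearing mate) is generated per feature and synthetic cell
# by resampling real reads: each synthetic UMI inherits the read multiplicity
# of a resampled real UMI, and each synthetic read takes a real read's 5'
# position plus a small uniform shift.  Read 1 is the 16-nt cell barcode
# followed by the 10-nt UMI.

#' Empirical reads-per-UMI distributions per feature
#'
#' For each feature, the real UMIs assigned to it (by the leftmost-read-5'
#' rule shared with [count_umis()]) are tabulated: the distribution of read
#' counts per UMI and, for each real UMI, the rows of its backing reads.
#' Features with no reads are flagged rather than given a distribution.
#'
#' @param reads read data.frame (`chrom`, `pos5`, `cell`, `umi`).
#' @param features disjoint interval table.
#' @return object of class `reads_per_umi`: list with `feature_ids`,
#'   `dist` (per feature: list(read_rows = list of integer vectors,
#'   c = reads per real UMI)), and `empty` (ids of read-free features).
#' @export
summarize_reads_per_umi <- function(reads, features) {
  fi <- .assign_to_feature(reads$chrom, reads$pos5, features)
  keep <- which(!is.na(fi) & !is.na(reads$umi) & !is.na(reads$cell))
  key <- paste(reads$cell[keep], reads$umi[keep], sep = "\r")
  # a UMI belongs to the feature of its leftmost-5' read
  ord <- keep[order(key, reads$chrom[keep], reads$pos5[keep])]
  key_ord <- paste(reads$cell[ord], reads$umi[ord], sep = "\r")
  umi_feat <- fi[ord][!duplicated(key_ord)]
  names(umi_feat) <- key_ord[!duplicated(key_ord)]
  dist <- vector("list", nrow(features))
  names(dist) <- features$id
  grp_feat <- umi_feat[paste(reads$cell[keep], reads$umi[keep], sep = "\r")]
  by_feat <- split(keep, grp_feat)
  for (fstr in names(by_feat)) {
    rows <- by_feat[[fstr]]
    f <- as.integer(fstr)
    umis <- split(rows, paste(reads$cell[rows], reads$umi[rows], sep = "\r"))
    dist[[f]] <- list(read_rows = unname(umis),
                      c = lengths(unname(umis)))
  }
  structure(list(feature_ids = features$id, dist = dist,
                 empty = features$id[vapply(dist, is.null, TRUE)]),
            class = "reads_per_umi")
}

#' Empirical pmf of reads-per-UMI for one feature
#' @param x a `reads_per_umi` object.
#' @param feature_id feature identifier.
#' @return named numeric vector (support value -> probability), or `NULL`
#'   for a read-free feature.
#' @export
reads_per_umi_pmf <- function(x, feature_id) {
  d <- x$dist[[feature_id]]
  if (is.null(d)) return(NULL)
  tb <- table(d$c)
  stats::setNames(as.numeric(tb) / sum(tb), names(tb))
}

.random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n)
  apply(m, 1L, paste0, collapse = "")
}

# clip a 5' position so the read of length len fits in [0, size)
.clip_pos5 <- function(pos5, len, strand, size) {
  ifelse(strand == "-",
         pmin(pmax(pos5, len - 1L), size - 1L),
         pmin(pmax(pos5, 0L), size - len))
}

#' Generate synthetic scRNA-seq reads 2 (genome mode)
#'
#' For each feature and synthetic cell with UMI count `u`, `u` synthetic
#' UMIs are created; each inherits the read multiplicity `c` of a real UMI
#' resampled (with replacement) from the feature's real UMIs, and its `c`
#' reads take real reads' 5' positions plus independent integer shifts drawn
#' uniformly from `-shift_range..shift_range`.  Strand is copied from the
#' source read; positions are clipped to chromosome bounds.  Sequences are
#' extracted from the genome strand-aware.
#'
#' @param umi_matrix synthetic feature-by-cell UMI matrix (rownames must
#'   match `features$id`).
#' @param rpu a `reads_per_umi` object from [summarize_reads_per_umi()].
#' @param reads the real read data.frame the distributions were built from.
#' @param features disjoint interval table.
#' @param genome named `DNAStringSet`, or `NULL` to skip sequence
#'   extraction.
#' @param read_len synthetic read length in nt (default 90).
#' @param shift_range maximum absolute 5' shift in nt (default 4).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame ledger with one row per synthetic read: `qname`,
#'   `chrom`, `pos5`, `len`, `strand`, `cell` (synthetic cell column name),
#'   `feature`, `umi_idx`, `src_pos5`, `shift`, `seq` (when `genome` given).
#' @export
synthesize_rna_reads <- function(umi_matrix, rpu, reads, features, genome,
                                 read_len = 90L, shift_range = 4L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(identical(rownames(umi_matrix), features$id))
  sizes <- if (!is.null(genome)) chrom_sizes(genome) else NULL
  cells <- colnames(umi_matrix)
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    u <- umi_matrix[i, ]
    tot_u <- sum(u)
    if (tot_u == 0L) next
    fid <- features$id[i]
    d <- rpu$dist[[fid]]
    cell_of_umi <- rep(cells[u > 0L], u[u > 0L])
    umi_idx <- sequence(u[u > 0L])
    if (is.null(d)) {
      warning("feature ", fid,
              " has synthetic counts but no real reads; placing reads ",
              "uniformly within the feature")
      n <- tot_u
      pos5 <- features$start[i] +
        sample.int(max(features$end[i] - features$start[i], 1L), n,
                   replace = TRUE) - 1L
      rec <- data.frame(chrom = features$chrom[i], pos5 = pos5,
                        strand = "+", cell = cell_of_umi,
                        feature = fid, umi_idx = umi_idx,
                        src_pos5 = NA_integer_, shift = NA_integer_,
                        stringsAsFactors = FALSE)
    } else {
      # resampling a real UMI uniformly draws its read count c from the
      # empirical reads-per-UMI distribution of the feature
      src_umi <- sample.int(length(d$c), tot_u, replace = TRUE)
      cvec <- d$c[src_umi]
      rows <- unlist(lapply(seq_len(tot_u), function(j) {
        rr <- d$read_rows[[src_umi[j]]]
        rr[sample.int(length(rr), cvec[j], replace = TRUE)]
      }))
      shift <- sample.int(2L * shift_range + 1L, length(rows),
                          replace = TRUE) - shift_range - 1L
      rec <- data.frame(chrom = reads$chrom[rows],
                        pos5 = reads$pos5[rows] + shift,
                        strand = reads$strand[rows],
                        cell = rep(cell_of_umi, cvec),
                        feature = fid,
                        umi_idx = rep(umi_idx, cvec),
                        src_pos5 = reads$pos5[rows],
                        shift = shift,
                        stringsAsFactors = FALSE)
    }
    out[[i]] <- rec
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chrom = character(), pos5 = integer(),
                      strand = character(), cell = character(),
                      feature = character(), umi_idx = integer(),
                      src_pos5 = integer(), shift = integer(),
                      len = integer(), qname = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  out$len <- read_len
  if (!is.null(sizes)) {
    out$pos5 <- .clip_pos5(out$pos5, out$len, out$strand,
                           as.integer(sizes[out$chrom]))
  }
  out$qname <- sprintf("rna_%07d", seq_len(nrow(out)))
  if (!is.null(genome) && nrow(out) > 0L) {
    left <- .leftmost(out$pos5, out$len, out$strand)
    out$seq <- extract_sequence(genome, out$chrom, left, left + out$len,
                                out$strand)
  }
  rownames(out) <- NULL
  out
}

#' Generate synthetic read-1 records (cell barcode + UMI)
#'
#' Every synthetic cell receives one random 16-nt barcode (resampled on
#' collision so barcodes are unique across cells); every synthetic UMI of a
#' (feature, cell) receives a fresh random 10-nt UMI shared by its reads 2.
#' Read 1 is the barcode concatenated with the UMI (default 26 nt) with
#' quality 37 (`'F'`) at every base.
#'
#' @param ledger read-2 ledger from [synthesize_rna_reads()].
#' @param barcode_len,umi_len barcode and UMI lengths (defaults 16, 10).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list with `records` (data.frame name/seq/qual aligned with the
#'   ledger rows) and `whitelist` (cell -> barcode data.frame).
#' @export
synthesize_read1 <- function(ledger, barcode_len = 16L, umi_len = 10L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- unique(ledger$cell)
  bc <- .random_dna(length(cells), barcode_len)
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- .random_dna(sum(dup), barcode_len)
  }
  names(bc) <- cells
  key <- paste(ledger$cell, ledger$feature, ledger$umi_idx, sep = "\r")
  ukey <- unique(key)
  umis <- .random_dna(length(ukey), umi_len)
  names(umis) <- ukey
  seq <- paste0(bc[ledger$cell], umis[key])
  records <- data.frame(name = ledger$qname, seq = seq,
                        qual = strrep("F", barcode_len + umi_len),
                        cell = ledger$cell,
                        barcode = unname(bc[ledger$cell]),
                        umi = unname(umis[key]),
                        stringsAsFactors = FALSE)
  list(records = records,
       whitelist = data.frame(cell = cells, barcode = unname(bc),
                              stringsAsFactors = FALSE))
}

#' Collapse each gene's transcripts into one transcript sequence
#'
#' The exons of all transcripts of a gene are unioned; the union segments
#' are concatenated in genomic order and reverse-complemented for
#' minus-strand genes.
#'
#' @param exons interval table of exons with `gene_id` and `strand`.
#' @param genome named `DNAStringSet`.
#' @return list with `seq` (named character vector per gene) and `len`
#'   (named integer vector of collapsed lengths).
#' @export
collapse_transcriptome <- function(exons, genome) {
  genes <- unique(exons$gene_id)
  seqs <- character(length(genes))
  names(seqs) <- genes
  for (g in genes) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    if (length(unique(e$strand[e$strand %in% c("+", "-")])) > 1L) {
      stop("gene ", g, " has exons on both strands")
    }
    red <- GenomicRanges::reduce(.gi2gr(e), ignore.strand = TRUE)
    red <- sort(red)
    parts <- extract_sequence(genome,
                              as.character(GenomicRanges::seqnames(red)),
                              GenomicRanges::start(red) - 1L,
                              GenomicRanges::end(red), "+")
    s <- paste0(parts, collapse = "")
    if (any(e$strand == "-")) {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    seqs[g] <- s
  }
  list(seq = seqs, len = stats::setNames(nchar(seqs), genes))
}

#' Generate synthetic scRNA-seq reads 2 (transcriptome mode)
#'
#' Synthetic read 5' starts are uniform over the collapsed transcript; the
#' read length is `min(read_len, l_i - start)` so no read crosses the
#' transcript boundary.
#'
#' @param umi_matrix synthetic gene-by-cell UMI matrix.
#' @param rpu `reads_per_umi` object (read multiplicities per UMI); genes
#'   without a distribution get 1 read per UMI.
#' @param collapsed output of [collapse_transcriptome()].
#' @param read_len maximum read length (default 90).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame ledger with `qname`, `feature`, `cell`, `umi_idx`,
#'   `start` (0-based on the collapsed transcript), `len`, `seq`.
#' @export
synthesize_rna_reads_transcriptome <- function(umi_matrix, rpu, collapsed,
                                               read_len = 90L,
                                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- colnames(umi_matrix)
  out <- vector("list", nrow(umi_matrix))
  for (i in seq_len(nrow(umi_matrix))) {
    u <- umi_matrix[i, ]
    tot_u <- sum(u)
    if (tot_u == 0L) next
    fid <- rownames(umi_matrix)[i]
    if (!fid %in% names(collapsed$seq)) {
      stop("gene ", fid, " missing from the collapsed transcriptome")
    }
    li <- unname(collapsed$len[fid])
    d <- rpu$dist[[fid]]
    cvec <- if (is.null(d)) {
      rep(1L, tot_u)
    } else {
      d$c[sample.int(length(d$c), tot_u, replace = TRUE)]
    }
    n <- sum(cvec)
    start <- sample.int(li, n, replace = TRUE) - 1L
    len <- pmin(read_len, li - start)
    cell_of_umi <- rep(cells[u > 0L], u[u > 0L])
    out[[i]] <- data.frame(
      feature = fid,
      cell = rep(cell_of_umi, cvec),
      umi_idx = rep(sequence(u[u > 0L]), cvec),
      start = start, len = len,
      seq = substring(collapsed$seq[fid], start + 1L, start + len),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(feature = character(), cell = character(),
                      umi_idx = integer(), start = integer(),
                      len = integer(), seq = character(),
                      qname = character(), stringsAsFactors = FALSE))
  }
  out$qname <- sprintf("rnatx_%07d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
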