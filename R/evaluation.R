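# Desk-computable comparison statistics between synthetic and reference
# read sets / count matrices.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM_i = n_i * 1e6 / (N * l_i)` with `l_i` the feature length in
#' kilobases and `N = sum(n_i)` the total read count.
#'
#' @param counts per-feature read counts.
#' @param lengths_bp feature lengths in bp.
#' @param total optional total read count `N` (defaults to `sum(counts)`).
#' @return numeric vector of RPKM values.
#' @export
rpkm <- function(counts, lengths_bp, total = sum(counts)) {
  if (total <= 0) stop("total read count must be positive")
  if (any(lengths_bp <= 0)) stop("feature lengths must be positive")
  counts * 1e6 / (total * (lengths_bp / 1000))
}

#' Six summary statistics of a feature-by-cell count matrix
#'
#' Feature-level: mean, variance, coefficient of variation and zero
#' proportion across cells.  Cell-level: library size and zero proportion
#' across features.  The cv is `NA` where the mean is 0.
#'
#' @param mat feature-by-cell matrix.
#' @return list with data.frames `feature` and `cell`.
#' @export
summary_statistics <- function(mat) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  v <- apply(mat, 1L, stats::var)
  if (ncol(mat) == 1L) v <- rep(0, nrow(mat))
  cv <- ifelse(mu > 0, sqrt(v) / mu, NA_real_)
  feat <- data.frame(feature = rownames(mat), mean = mu, var = v, cv = cv,
                     zero_prop = rowMeans(mat == 0),
                     stringsAsFactors = FALSE)
  cell <- data.frame(cell = colnames(mat), library_size = colSums(mat),
                     zero_prop = colMeans(mat == 0),
                     stringsAsFactors = FALSE)
  rownames(feat) <- rownames(cell) <- NULL
  list(feature = feat, cell = cell)
}

#' k-mer spectrum of a read set
#'
#' Tabulates every length-`k` substring across the reads, then histograms
#' the occurrence counts: how many distinct k-mers occur 1x, 2x, ...
#'
#' @param seqs character vector of read sequences.
#' @param k k-mer length.
#' @return named integer vector: occurrence count -> number of distinct
#'   k-mers.
#' @export
kmer_spectrum <- function(seqs, k) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(stats::setNames(integer(), character()))
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }))
  occ <- table(kmers)
  tb <- table(as.integer(occ))
  stats::setNames(as.integer(tb), names(tb))
}

#' Fragment-size histogram of read pairs
#' @param pairs pair data.frame with a `frag` column.
#' @return named integer vector: fragment size -> number of pairs.
#' @export
fragment_size_distribution <- function(pairs) {
  if (nrow(pairs) == 0L) return(stats::setNames(integer(), character()))
  tb <- table(pairs$frag)
  stats::setNames(as.integer(tb), names(tb))
}

#' Match called peaks against ground-truth peaks
#'
#' A called peak is correct when it overlaps some ground-truth peak by at
#' least the threshold (default: half the minimum truth-peak length, the
#' convention used when scoring peak callers); a truth peak is recovered
#' when some called peak overlaps it by at least the threshold.
#'
#' @param called,truth interval tables.
#' @param threshold overlap threshold in bp; defaults to
#'   `floor(min truth length / 2)`.
#' @return list with `recall`, `precision`, `f1`, `threshold`,
#'   `matched_truth` and `correct_called` id vectors.
#' @export
match_called_peaks <- function(called, truth, threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- floor(min(truth$end - truth$start) / 2)
  }
  if (nrow(called) == 0L || nrow(truth) == 0L) {
    return(list(recall = 0, precision = 0, f1 = 0, threshold = threshold,
                matched_truth = character(), correct_called = character()))
  }
  cg <- .gi2gr(called)
  tg <- .gi2gr(truth)
  hits <- GenomicRanges::findOverlaps(cg, tg, ignore.strand = TRUE)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    cg[S4Vectors::queryHits(hits)], tg[S4Vectors::subjectHits(hits)]))
  good <- ov >= threshold
  correct_called <- unique(called$id[S4Vectors::queryHits(hits)[good]])
  matched_truth <- unique(truth$id[S4Vectors::subjectHits(hits)[good]])
  recall <- length(matched_truth) / nrow(truth)
  precision <- length(correct_called) / nrow(called)
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  list(recall = recall, precision = precision, f1 = f1,
       threshold = threshold, matched_truth = matched_truth,
       correct_called = correct_called)
}
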