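# Summarize aligned reads into feature-by-cell UMI (scRNA-seq) or read
# (scATAC-seq) count matrices.
#
# Assignment rule: a read belongs to the unique feature containing its
# 5'-most base; a UMI belongs to the feature of its leftmost-5' read.  With
# features tiling the genome this makes assignment unique and conserves the
# total count (a boundary-spanning read is never counted twice).

# map each read's 5' base to a feature index (NA when no feature covers it)
.assign_to_feature <- function(chrom, pos5, features) {
  gr_pos <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(pos5 + 1L, pos5 + 1L))
  hits <- GenomicRanges::findOverlaps(gr_pos, .gi2gr(features),
                                      ignore.strand = TRUE, select = "first")
  hits
}

.sparse_counts <- function(fi, ci, n_feat, n_cell, feat_ids, cells) {
  mat <- Matrix::sparseMatrix(i = fi, j = ci, x = rep(1, length(fi)),
                              dims = c(n_feat, n_cell),
                              dimnames = list(feat_ids, cells))
  methods::as(mat, "CsparseMatrix")
}

#' Count distinct UMIs per feature and cell
#'
#' Entry (i, c) is the number of distinct UMIs of cell c whose leftmost read
#' 5' end falls in feature i.  Reads missing a barcode or UMI are skipped
#' with a warning (or raise an error with `on_missing = "error"`).
#'
#' @param reads read data.frame (`chrom`, `pos5`, `cell`, `umi`).
#' @param features interval table; must be disjoint.
#' @param cells optional fixed barcode ordering (defaults to sorted barcodes
#'   observed in `reads`).
#' @param on_missing `"skip"` (default) or `"error"` for reads lacking
#'   barcode/UMI.
#' @return sparse feature-by-cell matrix with `count_kind` attribute "umi".
#' @export
count_umis <- function(reads, features, cells = NULL,
                       on_missing = c("skip", "error")) {
  on_missing <- match.arg(on_missing)
  if (nrow(features) == 0L) stop("empty feature list")
  miss <- is.na(reads$cell) | is.na(reads$umi)
  if (any(miss)) {
    if (on_missing == "error") stop(sum(miss), " reads missing barcode/UMI")
    warning(sum(miss), " reads missing barcode/UMI skipped")
    reads <- reads[!miss, , drop = FALSE]
  }
  if (is.null(cells)) cells <- sort(unique(reads$cell))
  # UMI -> feature of its leftmost-5' read (ties by chrom/pos ordering)
  ord <- order(reads$cell, reads$umi, reads$chrom, reads$pos5)
  r <- reads[ord, , drop = FALSE]
  first <- !duplicated(paste(r$cell, r$umi, sep = "\r"))
  r <- r[first, , drop = FALSE]
  fi <- .assign_to_feature(r$chrom, r$pos5, features)
  keep <- !is.na(fi) & r$cell %in% cells
  mat <- .sparse_counts(fi[keep], match(r$cell[keep], cells),
                        nrow(features), length(cells), features$id, cells)
  attr(mat, "count_kind") <- "umi"
  mat
}

#' Count read mates per feature and cell
#'
#' Each mate of a pair is counted individually in the feature containing its
#' own 5'-most base, so a proper pair fully inside a peak contributes 2.
#'
#' @param pairs pair data.frame.
#' @param features interval table; must be non-empty and disjoint.
#' @param cells optional fixed barcode ordering.
#' @return sparse feature-by-cell matrix with `count_kind` attribute "read".
#' @export
count_reads <- function(pairs, features, cells = NULL) {
  if (nrow(features) == 0L) stop("empty feature list")
  if (is.null(cells)) cells <- sort(unique(pairs$cell))
  chrom <- c(pairs$chrom, pairs$chrom)
  pos5 <- c(pairs$pos5_1, pairs$pos5_2)
  cell <- c(pairs$cell, pairs$cell)
  fi <- .assign_to_feature(chrom, pos5, features)
  keep <- !is.na(fi) & cell %in% cells
  mat <- .sparse_counts(fi[keep], match(cell[keep], cells),
                        nrow(features), length(cells), features$id, cells)
  attr(mat, "count_kind") <- "read"
  mat
}

#' Drop flagged cell columns from a matched matrix pair
#'
#' Both matrices (e.g. gene and inter-gene) lose exactly the given barcodes;
#' remaining column order is preserved, keeping the two matrices aligned.
#' Barcodes not present are ignored with a warning.
#'
#' @param matrix_pair list of two feature-by-cell matrices sharing identical
#'   column (barcode) ordering.
#' @param drop_barcodes character vector, e.g. detected doublets.
#' @return list of the two pruned matrices.
#' @export
remove_flagged_cells <- function(matrix_pair, drop_barcodes) {
  stopifnot(identical(colnames(matrix_pair[[1L]]),
                      colnames(matrix_pair[[2L]])))
  absent <- setdiff(drop_barcodes, colnames(matrix_pair[[1L]]))
  if (length(absent)) {
    warning("barcode(s) not present: ", paste(absent, collapse = ", "))
  }
  keep <- !(colnames(matrix_pair[[1L]]) %in% drop_barcodes)
  lapply(matrix_pair, function(m) m[, keep, drop = FALSE])
}
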