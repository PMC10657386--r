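# Synthetic scATAC-seq paired-end read generation.
#
# Mimic mode: for each trustworthy feature and synthetic cell with read
# count c, ceiling(c/2) real pairs overlapping the feature are resampled;
# each synthetic pair takes its source pair's strand configuration and
# fragment size, with one shared uniform shift applied to both mates' 5'
# positions.  Designed-truth mode first translates the source pair by the
# signed distance between the designed feature and its trustworthy donor.

#' Translate read pairs by per-pair signed distances
#'
#' Each pair's two 5' positions move by the same signed distance `d`
#' (fragment size unchanged).  Pairs whose span ends up entirely outside
#' the chromosome are dropped with a warning; the rest are clamped jointly
#' so both mates fit, preserving the fragment size.
#'
#' @param pairs pair data.frame.
#' @param d integer vector of signed distances (recycled).
#' @param sizes named chromosome lengths.
#' @return the translated pair table with a `dropped` attribute counting
#'   removed pairs.
#' @export
relocate_pairs <- function(pairs, d, sizes) {
  n <- nrow(pairs)
  if (n == 0L) return(pairs)
  d <- rep_len(as.integer(d), n)
  pairs$pos5_1 <- pairs$pos5_1 + d
  pairs$pos5_2 <- pairs$pos5_2 + d
  l1 <- .leftmost(pairs$pos5_1, pairs$len1, pairs$strand_1)
  l2 <- .leftmost(pairs$pos5_2, pairs$len2, pairs$strand_2)
  left <- pmin(l1, l2)
  right <- pmax(l1 + pairs$len1, l2 + pairs$len2)
  size <- as.integer(sizes[pairs$chrom])
  out_of_range <- right <= 0L | left >= size
  if (any(out_of_range)) {
    warning(sum(out_of_range), " relocated pair(s) fell outside the ",
            "chromosome and were dropped")
  }
  # clamp jointly so the whole pair fits; fragment size is preserved
  adj <- pmax(0L, -left) - pmax(0L, right - size)
  pairs$pos5_1 <- pairs$pos5_1 + adj
  pairs$pos5_2 <- pairs$pos5_2 + adj
  out <- pairs[!out_of_range, , drop = FALSE]
  attr(out, "dropped") <- sum(out_of_range)
  out
}

#' Generate synthetic scATAC-seq read pairs
#'
#' For every feature and synthetic cell, the synthetic read count `c` from
#' the count matrix yields `ceiling(c/2)` synthetic pairs resampled (with
#' replacement) from the real pairs overlapping the feature (a pair is
#' eligible when either mate's 5' base is assigned to the feature).  One
#' shared shift, uniform on `-shift_range..shift_range`, is added to both
#' mates' 5' positions so the fragment size is unchanged.  In designed-truth
#' mode (`mapping` given), source pairs come from each designed feature's
#' trustworthy donor and are first translated by the signed distance `d`.
#'
#' @param count_matrix synthetic feature-by-cell read-count matrix; rownames
#'   must match `features$id`.
#' @param real_pairs real pair data.frame.
#' @param features interval table the counts refer to (designed features in
#'   designed-truth mode).
#' @param genome named `DNAStringSet`, or `NULL` to skip sequences.
#' @param read_len synthetic read length (default 50).
#' @param shift_range maximum absolute shift (default 4).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param mapping optional mapping data.frame (`designed_id`, `donor_id`,
#'   `d`) from [map_designed_counts()].
#' @param donor_features trustworthy feature table (required with
#'   `mapping`); eligibility is evaluated against these.
#' @return pair data.frame with provenance columns `feature`, `src_frag`,
#'   `shift` and sequences `seq1`/`seq2` when `genome` is given.
#' @export
synthesize_atac_pairs <- function(count_matrix, real_pairs, features,
                                  genome, read_len = 50L, shift_range = 4L,
                                  seed = NULL, mapping = NULL,
                                  donor_features = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(features) == 0L ||
              identical(rownames(count_matrix), features$id))
  eligible_in <- if (is.null(mapping)) features else donor_features
  f1 <- .assign_to_feature(real_pairs$chrom, real_pairs$pos5_1, eligible_in)
  f2 <- .assign_to_feature(real_pairs$chrom, real_pairs$pos5_2, eligible_in)
  elig <- lapply(seq_len(nrow(eligible_in)),
                 function(i) which(f1 == i | f2 == i))
  names(elig) <- eligible_in$id
  sizes <- if (!is.null(genome)) chrom_sizes(genome) else NULL
  cells <- colnames(count_matrix)
  med_frag <- if (nrow(real_pairs)) {
    as.integer(stats::median(real_pairs$frag))
  } else 100L
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    cc <- count_matrix[i, ]
    npair <- ceiling(cc / 2)
    tot <- sum(npair)
    if (tot == 0L) next
    fid <- features$id[i]
    src_id <- if (is.null(mapping)) fid else {
      mapping$donor_id[mapping$designed_id == fid]
    }
    d_off <- if (is.null(mapping)) 0L else {
      as.integer(mapping$d[mapping$designed_id == fid])
    }
    rows <- elig[[src_id]]
    cell_of_pair <- rep(cells[npair > 0L], npair[npair > 0L])
    if (length(rows) == 0L) {
      warning("feature ", fid, " has synthetic counts but no real pairs; ",
              "placing pairs uniformly within the feature")
      left <- features$start[i] +
        sample.int(max(features$end[i] - features$start[i], 1L), tot,
                   replace = TRUE) - 1L
      rec <- data.frame(chrom = features$chrom[i],
                        pos5_1 = left, len1 = read_len, strand_1 = "+",
                        pos5_2 = left + med_frag - 1L, len2 = read_len,
                        strand_2 = "-",
                        cell = cell_of_pair, feature = fid,
                        src_frag = NA_integer_, shift = NA_integer_,
                        stringsAsFactors = FALSE)
    } else {
      pick <- rows[sample.int(length(rows), tot, replace = TRUE)]
      shift <- sample.int(2L * shift_range + 1L, tot, replace = TRUE) -
        shift_range - 1L
      rec <- data.frame(chrom = real_pairs$chrom[pick],
                        pos5_1 = real_pairs$pos5_1[pick] + d_off + shift,
                        len1 = read_len,
                        strand_1 = real_pairs$strand_1[pick],
                        pos5_2 = real_pairs$pos5_2[pick] + d_off + shift,
                        len2 = read_len,
                        strand_2 = real_pairs$strand_2[pick],
                        cell = cell_of_pair, feature = fid,
                        src_frag = real_pairs$frag[pick],
                        shift = shift,
                        stringsAsFactors = FALSE)
    }
    out[[i]] <- rec
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos5_1 = integer(),
                      len1 = integer(), strand_1 = character(),
                      pos5_2 = integer(), len2 = integer(),
                      strand_2 = character(), cell = character(),
                      feature = character(), src_frag = integer(),
                      shift = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(sizes) && nrow(out) > 0L) {
    out <- relocate_pairs(out, 0L, sizes)
  }
  out$frag <- fragment_size(out)
  out$qname <- sprintf("atac_%07d", seq_len(max(nrow(out), 0L)))
  if (!is.null(genome)) {
    if (nrow(out) > 0L) {
      l1 <- .leftmost(out$pos5_1, out$len1, out$strand_1)
      l2 <- .leftmost(out$pos5_2, out$len2, out$strand_2)
      out$seq1 <- extract_sequence(genome, out$chrom, l1, l1 + out$len1,
                                   out$strand_1)
      out$seq2 <- extract_sequence(genome, out$chrom, l2, l2 + out$len2,
                                   out$strand_2)
    } else {
      out$seq1 <- character()
      out$seq2 <- character()
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign unique cell barcodes to synthetic ATAC pairs
#'
#' Each synthetic cell receives one random 16-nt barcode shared by all its
#' reads; collisions across cells are resampled away so the emitted
#' whitelist contains unique barcodes.
#'
#' @param pairs pair data.frame with a `cell` column.
#' @param barcode_len barcode length (default 16).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list with `pairs` (barcode column added) and `whitelist`.
#' @export
assign_atac_barcodes <- function(pairs, barcode_len = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- unique(pairs$cell)
  bc <- .random_dna(length(cells), barcode_len)
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- .random_dna(sum(dup), barcode_len)
  }
  names(bc) <- cells
  pairs$barcode <- unname(bc[pairs$cell])
  list(pairs = pairs,
       whitelist = data.frame(cell = cells, barcode = unname(bc),
                              stringsAsFactors = FALSE))
}
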