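# Brute-force per-base oracles used to cross-check the interval algebra,
# plus tiny shared fixture builders.  The oracles deliberately avoid the
# package's own GenomicRanges-based code paths.

# per-base union -> maximal runs (merged intervals) on one chromosome
bf_merge_chrom <- function(starts, ends, max_end = max(ends)) {
  covered <- logical(max_end)
  for (i in seq_along(starts)) {
    covered[(starts[i] + 1L):ends[i]] <- TRUE
  }
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  data.frame(start = begins[keep] - 1L, end = stops[keep])
}

# per-base complement of disjoint features on a chromosome of given length
bf_complement_chrom <- function(starts, ends, len) {
  covered <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1L):ends[i]] <- TRUE
  }
  r <- rle(!covered)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  data.frame(start = begins[keep] - 1L, end = stops[keep])
}

# per-base covered length of [s, e) by a union of reference intervals
bf_covered_length <- function(s, e, ref_starts, ref_ends, len) {
  covered <- logical(len)
  for (i in seq_along(ref_starts)) {
    if (ref_ends[i] > ref_starts[i]) {
      covered[(ref_starts[i] + 1L):ref_ends[i]] <- TRUE
    }
  }
  sum(covered[(s + 1L):e])
}

# per-base peak matching: overlap of every (called, truth) pair
bf_match_peaks <- function(called, truth, threshold) {
  ov <- function(a_s, a_e, b_s, b_e) max(0L, min(a_e, b_e) - max(a_s, b_s))
  correct <- logical(nrow(called))
  matched <- logical(nrow(truth))
  for (i in seq_len(nrow(called))) {
    for (j in seq_len(nrow(truth))) {
      if (called$chrom[i] == truth$chrom[j] &&
          ov(called$start[i], called$end[i],
             truth$start[j], truth$end[j]) >= threshold) {
        correct[i] <- TRUE
        matched[j] <- TRUE
      }
    }
  }
  recall <- mean(matched)
  precision <- mean(correct)
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  list(recall = recall, precision = precision, f1 = f1)
}

# small shared RNA fixture (built once per test run)
toy_rna <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- make_toy_genome(2L, 5e4, seed = 101L)
      sizes <- chrom_sizes(genome)
      ann <- make_toy_annotation(sizes, n_genes = 10L,
                                 overlap_fraction = 0.4, seed = 101L)
      feat <- merge_overlapping_genes(ann$genes)
      fx <- make_toy_scrna_reads(genome, feat, n_cells = 12L,
                                 error_rate = 0, seed = 102L)
      cache <<- list(genome = genome, sizes = sizes, ann = ann,
                     features = feat, fx = fx)
    }
    cache
  }
})

# small shared ATAC fixture
toy_atac <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- make_toy_genome(1L, 1e5, seed = 201L)
      sizes <- chrom_sizes(genome)
      peaks <- intervals(rep("chr1", 8L), seq(5000L, 75000L, by = 10000L),
                         seq(5000L, 75000L, by = 10000L) + 500L,
                         label = "peak", id = sprintf("peak_%d", 1:8))
      fx <- make_toy_scatac_reads(genome, peaks, n_cells = 10L,
                                  frags_per_cell = 250L,
                                  enrichment_ratio = 40, seed = 202L)
      cache <<- list(genome = genome, sizes = sizes, peaks = peaks,
                     fx = fx)
    }
    cache
  }
})
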