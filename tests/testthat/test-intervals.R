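# Genome partitioning: gene merging, complements, the ATAC three-way
# partition, half-length overlap selection, the coverage-window region
# caller and TSS-anchored truth-peak design.

test_that("overlapping genes aggregate into supergenes", {
  g <- intervals(c("chr1", "chr1"), c(100L, 150L), c(200L, 300L),
                 id = c("gA", "gB"))
  m <- merge_overlapping_genes(g)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 300L)
  expect_equal(m$n_members, 2L)
  expect_setequal(strsplit(m$members, ",")[[1]], c("gA", "gB"))

  disjoint <- intervals(c("chr1", "chr1"), c(0L, 60L), c(50L, 90L),
                        id = c("g1", "g2"))
  md <- merge_overlapping_genes(disjoint)
  expect_equal(md[, c("start", "end")], disjoint[, c("start", "end")])
  expect_equal(md$id, disjoint$id)

  empty <- merge_overlapping_genes(intervals(character(), integer(),
                                             integer()))
  expect_equal(nrow(empty), 0L)

  bad <- data.frame(chrom = "chr1", start = 10L, end = 10L, strand = "*",
                    label = NA, id = "x")
  expect_error(merge_overlapping_genes(bad), "invalid interval")
})

test_that("gene merging agrees with a per-base brute-force sweep", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 15L
    s <- sample.int(9000L, n)
    e <- s + sample.int(800L, n)
    g <- intervals(rep("chr1", n), s, e, id = sprintf("g%d", 1:n))
    m <- merge_overlapping_genes(g)
    bf <- bf_merge_chrom(g$start, g$end)
    expect_equal(m$start, bf$start)
    expect_equal(m$end, bf$end)
  }
})

test_that("interval complement tiles the chromosome", {
  sizes <- c(chr1 = 500L)
  f <- intervals("chr1", 100L, 200L, id = "f1")
  comp <- complement_intervals(f, sizes)
  expect_equal(comp$start, c(0L, 200L))
  expect_equal(comp$end, c(100L, 500L))

  tiling <- intervals(c("chr1", "chr1"), c(0L, 200L), c(200L, 500L))
  expect_equal(nrow(complement_intervals(tiling, sizes)), 0L)

  # chromosome with no features -> whole chromosome
  two <- c(chr1 = 500L, chr2 = 300L)
  comp2 <- complement_intervals(f, two)
  expect_equal(comp2[comp2$chrom == "chr2", ]$start, 0L)
  expect_equal(comp2[comp2$chrom == "chr2", ]$end, 300L)

  expect_error(complement_intervals(intervals("chr1", 400L, 600L), sizes),
               "bounds")
})

test_that("complement is an involution and matches brute force", {
  set.seed(11)
  sizes <- c(chr1 = 10000L)
  for (rep in 1:5) {
    # random disjoint features
    cuts <- sort(sample.int(9999L, 8L))
    f <- intervals(rep("chr1", 4L), cuts[c(1, 3, 5, 7)],
                   cuts[c(2, 4, 6, 8)])
    comp <- complement_intervals(f, sizes)
    bf <- bf_complement_chrom(f$start, f$end, 10000L)
    expect_equal(comp$start, bf$start)
    expect_equal(comp$end, bf$end)
    back <- complement_intervals(comp, sizes)
    expect_equal(back[, c("start", "end")],
                 merge_overlapping_genes(f)[, c("start", "end")])
  }
})

test_that("ATAC partition labels peaks, non-peaks and gray areas", {
  sizes <- c(chr1 = 500L)
  p <- intervals("chr1", 100L, 200L, label = "peak", id = "p1")
  np <- intervals("chr1", 300L, 400L, label = "nonpeak", id = "n1")
  part <- build_atac_partition(p, np, sizes)
  expect_s3_class(part, "genome_partition")
  expect_equal(part$gray$start, c(0L, 200L, 400L))
  expect_equal(part$gray$end, c(100L, 300L, 500L))
  # completeness: lengths sum to the chromosome, no overlaps
  all_iv <- rbind(part$peaks[, c("start", "end")],
                  part$nonpeaks[, c("start", "end")],
                  part$gray[, c("start", "end")])
  expect_equal(sum(all_iv$end - all_iv$start), 500L)
  all_iv <- all_iv[order(all_iv$start), ]
  expect_true(all(all_iv$start[-1] >= all_iv$end[-nrow(all_iv)]))

  tile_np <- intervals(c("chr1", "chr1"), c(0L, 200L), c(100L, 500L),
                       id = c("n1", "n2"))
  part2 <- build_atac_partition(p, tile_np, sizes)
  expect_equal(nrow(part2$gray), 0L)

  bad_np <- intervals("chr1", 150L, 250L, id = "n1")
  expect_error(build_atac_partition(p, bad_np, sizes), "conflicting")
})

test_that("half-length overlap rule selects trustworthy candidates", {
  cand <- intervals("chr1", 0L, 100L, id = "c1")
  expect_equal(nrow(select_trustworthy_by_overlap(
    cand, intervals("chr1", 0L, 50L))), 1L)
  expect_equal(nrow(select_trustworthy_by_overlap(
    cand, intervals("chr1", 0L, 49L))), 0L)
  expect_equal(nrow(select_trustworthy_by_overlap(cand, cand)), 1L)
})

test_that("overlap selection agrees with per-base coverage counting", {
  set.seed(13)
  for (rep in 1:5) {
    nc <- 10L
    cs <- sample.int(9000L, nc)
    cand <- intervals(rep("chr1", nc), cs, cs + sample.int(500L, nc),
                      id = sprintf("c%d", 1:nc))
    rs <- sample.int(9000L, 12L)
    ref <- intervals(rep("chr1", 12L), rs, rs + sample.int(700L, 12L))
    got <- select_trustworthy_by_overlap(cand, ref)
    want <- vapply(seq_len(nc), function(i) {
      cov <- bf_covered_length(cand$start[i], cand$end[i],
                               ref$start, ref$end, 10000L)
      2L * cov >= (cand$end[i] - cand$start[i])
    }, logical(1))
    expect_setequal(got$id, cand$id[want])
  }
})

test_that("coverage-window caller separates enrichment from background", {
  set.seed(17)
  sizes <- c(chr1 = 50000L)
  # flat background: no stringent peaks
  flat <- data.frame(chrom = "chr1",
                     pos5 = sample.int(50000L, 2000L, TRUE) - 1L)
  res_flat <- call_regions_by_coverage(flat, sizes, window = 500L)
  expect_equal(nrow(res_flat$peaks), 0L)
  expect_gt(sum(res_flat$nonpeaks$end - res_flat$nonpeaks$start), 45000L)

  # one window at ~100x background density
  hot <- data.frame(chrom = "chr1",
                    pos5 = 10000L + sample.int(500L, 4000L, TRUE) - 1L)
  res_hot <- call_regions_by_coverage(rbind(flat, hot), sizes,
                                      window = 500L)
  expect_true(any(res_hot$peaks$start <= 10000L &
                    res_hot$peaks$end >= 10500L))

  # stringent peaks are always inside relaxed peaks => never in non-peaks
  ov <- GenomicRanges::findOverlaps(
    screads:::.gi2gr(res_hot$peaks), screads:::.gi2gr(res_hot$nonpeaks))
  expect_equal(length(ov), 0L)

  expect_error(call_regions_by_coverage(flat[0, ], sizes), "empty")
  expect_error(call_regions_by_coverage(flat, sizes, stringent_q = 0.2,
                                        relaxed_q = 0.1), "stringent")
})

test_that("TSS-anchored truth peaks honour length law and merging", {
  sizes <- c(chr1 = 10000L)
  one <- design_tss_peaks(data.frame(chrom = "chr1", pos = 1000L), sizes,
                          min_len = 300L, max_len = 300L, seed = 1L)
  expect_equal(one$start, 1000L)
  expect_equal(one$end, 1300L)

  two <- design_tss_peaks(data.frame(chrom = "chr1",
                                     pos = c(2000L, 2100L)), sizes,
                          min_len = 300L, max_len = 300L, seed = 1L)
  expect_equal(nrow(two), 1L)
  expect_equal(two$start, 2000L)
  expect_equal(two$end, 2400L)

  many <- design_tss_peaks(
    data.frame(chrom = "chr1", pos = seq(100L, 9000L, by = 700L)),
    sizes, seed = 5L)
  lens <- many$end - many$start
  # merged peaks can exceed 550 but no single draw leaves [250, 550]
  expect_true(all(lens >= 250L))
  expect_identical(many,
                   design_tss_peaks(
                     data.frame(chrom = "chr1",
                                pos = seq(100L, 9000L, by = 700L)),
                     sizes, seed = 5L))
  expect_error(design_tss_peaks(data.frame(chrom = "chr1", pos = 10001L),
                                sizes), "bounds")
})
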