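# scRNA-seq read synthesis: reads-per-UMI law, genome-mode resampling with
# bounded shifts, read-1 construction and transcriptome mode.

test_that("reads-per-UMI distributions tabulate real UMIs", {
  feat <- intervals("chr1", 0L, 1000L, id = "G")
  reads <- data.frame(chrom = "chr1",
                      pos5 = c(10L, 20L, 100L, 110L, 200L),
                      len = 10L, strand = "+", cell = "c1",
                      umi = c("U1", "U1", "U2", "U3", "U3"),
                      stringsAsFactors = FALSE)
  # U1 has 2 reads, U2 has 1, U3 has 2 -> pmf {1: 1/3, 2: 2/3}
  rpu <- summarize_reads_per_umi(reads, feat)
  pmf <- reads_per_umi_pmf(rpu, "G")
  expect_equal(unname(pmf[c("1", "2")]), c(1 / 3, 2 / 3))

  single <- summarize_reads_per_umi(
    data.frame(chrom = "chr1", pos5 = rep(5L, 5), len = 10L,
               strand = "+", cell = "c1", umi = "U9",
               stringsAsFactors = FALSE), feat)
  expect_equal(reads_per_umi_pmf(single, "G"), c("5" = 1))

  feat2 <- rbind(feat, intervals("chr2", 0L, 500L, id = "H"))
  rpu2 <- summarize_reads_per_umi(reads, feat2)
  expect_true("H" %in% rpu2$empty)
  expect_null(reads_per_umi_pmf(rpu2, "H"))
})

test_that("synthetic reads honour counts, UMI multiplicities and shifts", {
  tr <- toy_rna()
  rpu <- summarize_reads_per_umi(tr$fx$reads, tr$features)
  synth <- tr$fx$umi_matrix[, 1:6]
  colnames(synth) <- sprintf("s%d", 1:6)
  led <- synthesize_rna_reads(synth, rpu, tr$fx$reads, tr$features,
                              tr$genome, seed = 7L)
  # ledger tabulation reproduces the synthetic UMI matrix exactly
  umi_tab <- tapply(led$umi_idx,
                    list(factor(led$feature, levels = rownames(synth)),
                         factor(led$cell, levels = colnames(synth))),
                    function(z) length(unique(z)))
  umi_tab[is.na(umi_tab)] <- 0
  expect_equal(unname(umi_tab), unname(as.matrix(synth)))
  # every read within +/-4 of its source 5' position
  expect_true(all(abs(led$pos5 - led$src_pos5) <= 4L))
  expect_true(all(led$shift %in% -4:4))
  # sequences equal the strand-aware reference substring
  left <- ifelse(led$strand == "-", led$pos5 - led$len + 1L, led$pos5)
  expect_equal(led$seq,
               extract_sequence(tr$genome, led$chrom, left,
                                left + led$len, led$strand))
  expect_true(all(led$len == 90L))
})

test_that("zero counts and degenerate laws behave as constructed", {
  feat <- intervals("chr1", 0L, 2000L, id = "G")
  reads <- data.frame(chrom = "chr1", pos5 = seq(100L, 500L, by = 50L),
                      len = 20L, strand = "+", cell = "c1",
                      umi = sprintf("U%d", 1:9),
                      stringsAsFactors = FALSE)  # every UMI has 1 read
  rpu <- summarize_reads_per_umi(reads, feat)
  genome <- make_toy_genome(1L, 3000L, seed = 1L)

  zero <- matrix(0L, 1, 2, dimnames = list("G", c("s1", "s2")))
  expect_equal(nrow(synthesize_rna_reads(zero, rpu, reads, feat, genome,
                                         seed = 1L)), 0L)

  seven <- matrix(c(7L, 0L), 1, 2, dimnames = list("G", c("s1", "s2")))
  led <- synthesize_rna_reads(seven, rpu, reads, feat, genome, seed = 2L)
  expect_equal(nrow(led), 7L)            # degenerate law: 1 read per UMI
  expect_equal(length(unique(led$umi_idx)), 7L)

  # feature with counts but no reads: uniform fallback with a warning
  feat2 <- rbind(feat, intervals("chr1", 2000L, 2500L, id = "H"))
  m2 <- matrix(c(0L, 3L), 2, 1, dimnames = list(c("G", "H"), "s1"))
  expect_warning(
    led2 <- synthesize_rna_reads(m2, summarize_reads_per_umi(reads, feat2),
                                 reads, feat2, genome, read_len = 20L,
                                 seed = 3L),
    "no real reads")
  expect_equal(nrow(led2), 3L)
  expect_true(all(led2$pos5 >= 2000L & led2$pos5 < 2500L))
})

test_that("read 1 concatenates a shared barcode with per-UMI tags", {
  tr <- toy_rna()
  rpu <- summarize_reads_per_umi(tr$fx$reads, tr$features)
  synth <- tr$fx$umi_matrix[, 1:4]
  colnames(synth) <- sprintf("s%d", 1:4)
  led <- synthesize_rna_reads(synth, rpu, tr$fx$reads, tr$features,
                              tr$genome, seed = 11L)
  r1 <- synthesize_read1(led, seed = 12L)
  expect_true(all(nchar(r1$records$seq) == 26L))
  expect_true(all(strsplit(paste(r1$records$seq, collapse = ""),
                           "")[[1]] %in% c("A", "C", "G", "T")))
  # one barcode per synthetic cell, unique across cells
  per_cell <- tapply(r1$records$barcode, r1$records$cell,
                     function(z) length(unique(z)))
  expect_true(all(per_cell == 1L))
  expect_equal(anyDuplicated(r1$whitelist$barcode), 0L)
  # reads of the same synthetic UMI share the full read-1 string
  key <- paste(led$cell, led$feature, led$umi_idx)
  per_umi <- tapply(r1$records$seq, key, function(z) length(unique(z)))
  expect_true(all(per_umi == 1L))
})

test_that("transcript collapsing unions exons strand-aware", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "AACGTT", strrep("ACGT", 10))))
  ex1 <- data.frame(chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L),
                    strand = "+", gene_id = "g1",
                    stringsAsFactors = FALSE)
  col1 <- collapse_transcriptome(ex1, genome)
  expect_equal(unname(col1$len[["g1"]]), 20L)
  expect_equal(unname(col1$seq[["g1"]]),
               extract_sequence(genome, "chr1", 10L, 30L, "+"))

  # single exon over "AACG" on the minus strand -> "CGTT"
  ex2 <- data.frame(chrom = "chr1", start = 0L, end = 4L, strand = "-",
                    gene_id = "g2", stringsAsFactors = FALSE)
  expect_equal(unname(collapse_transcriptome(ex2, genome)$seq[["g2"]]),
               "CGTT")

  ex3 <- data.frame(chrom = "chr1", start = c(0L, 10L), end = c(4L, 14L),
                    strand = c("+", "-"), gene_id = "g3",
                    stringsAsFactors = FALSE)
  expect_error(collapse_transcriptome(ex3, genome), "both strands")
})

test_that("transcriptome mode clips at the collapsed boundary", {
  genome <- make_toy_genome(1L, 5000L, seed = 5L)
  ex <- data.frame(chrom = "chr1", start = 100L, end = 200L, strand = "+",
                   gene_id = "g1", stringsAsFactors = FALSE)
  col <- collapse_transcriptome(ex, genome)   # l = 100
  rpu <- structure(list(feature_ids = "g1",
                        dist = stats::setNames(list(NULL), "g1"),
                        empty = "g1"), class = "reads_per_umi")
  m <- matrix(400L, 1, 1, dimnames = list("g1", "s1"))
  led <- synthesize_rna_reads_transcriptome(m, rpu, col, read_len = 90L,
                                            seed = 6L)
  expect_equal(nrow(led), 400L)
  expect_true(all(led$len == pmin(90L, 100L - led$start)))
  expect_true(all(led$start + led$len <= 100L))
  expect_true(all(nchar(led$seq) == led$len))

  expect_error(synthesize_rna_reads_transcriptome(
    matrix(1L, 1, 1, dimnames = list("gX", "s1")), rpu, col),
    "missing from the collapsed")
})
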