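# scATAC-seq pair synthesis: ceiling(c/2) pair counts, fragment-size
# preservation under the shared shift, designed-truth relocation and
# barcode assignment.

test_that("pair counts follow ceiling(c/2) and fragments are preserved", {
  ta <- toy_atac()
  cm <- count_reads(ta$fx$pairs, ta$peaks, cells = ta$fx$cells)
  cm <- as.matrix(cm)[, 1:5]
  colnames(cm) <- sprintf("s%d", 1:5)
  syn <- synthesize_atac_pairs(cm, ta$fx$pairs, ta$peaks, ta$genome,
                               seed = 21L)
  expect_equal(nrow(syn), sum(ceiling(cm / 2)))
  per <- table(factor(syn$feature, levels = rownames(cm)),
               factor(syn$cell, levels = colnames(cm)))
  expect_equal(unname(unclass(per)), unname(ceiling(cm / 2)),
               ignore_attr = TRUE)
  # fragment size equals the source pair's fragment size exactly
  expect_true(all(syn$frag == syn$src_frag))
  # shared shift: both mates within +/-4 of a common translate
  expect_true(all(syn$shift %in% -4:4))
  # sequences come from the genome at the mates' strand-aware intervals
  l1 <- ifelse(syn$strand_1 == "-", syn$pos5_1 - syn$len1 + 1L, syn$pos5_1)
  expect_equal(syn$seq1,
               extract_sequence(ta$genome, syn$chrom, l1, l1 + syn$len1,
                                syn$strand_1))
})

test_that("zero counts emit nothing and odd counts round up", {
  ta <- toy_atac()
  cm <- matrix(c(0L, 5L), 2, 1,
               dimnames = list(ta$peaks$id[1:2], "s1"))
  syn <- synthesize_atac_pairs(cm, ta$fx$pairs, ta$peaks[1:2, ],
                               ta$genome, seed = 22L)
  expect_equal(nrow(syn), 3L)            # ceiling(5/2)
  expect_equal(sum(syn$feature == ta$peaks$id[1]), 0L)
  expect_equal(2L * nrow(syn), 6L)       # mates
})

test_that("relocation translates pairs by d and keeps fragments", {
  pairs <- data.frame(qname = "p1", chrom = "chr1",
                      pos5_1 = 1000L, len1 = 50L, strand_1 = "+",
                      pos5_2 = 1150L, len2 = 50L, strand_2 = "-",
                      cell = "c1", stringsAsFactors = FALSE)
  pairs$frag <- fragment_size(pairs)
  sizes <- c(chr1 = 10000L)
  moved <- relocate_pairs(pairs, 100L, sizes)
  expect_equal(moved$pos5_1, 1100L)
  expect_equal(moved$pos5_2, 1250L)
  expect_equal(fragment_size(moved), pairs$frag)

  same <- relocate_pairs(pairs, 0L, sizes)
  expect_equal(same$pos5_1, pairs$pos5_1)

  expect_warning(gone <- relocate_pairs(pairs, -5000L, sizes), "dropped")
  expect_equal(nrow(gone), 0L)
  expect_equal(attr(gone, "dropped"), 1L)

  # signed distance convention: start(designed) - start(donor)
  designed <- intervals("chr1", 5000L, 5400L, id = "d1")
  donor <- intervals("chr1", 3000L, 3400L, id = "t1")
  expect_equal(designed$start - donor$start, 2000L)
})

test_that("designed-truth synthesis relocates donor reads", {
  ta <- toy_atac()
  donor <- ta$peaks[3, , drop = FALSE]
  designed <- intervals("chr1", donor$start + 30000L,
                        donor$end + 30000L, label = "gt_peak", id = "d1")
  mapping <- data.frame(designed_id = "d1", donor_id = donor$id,
                        d = 30000L, stringsAsFactors = FALSE)
  cm <- matrix(20L, 1, 2, dimnames = list("d1", c("s1", "s2")))
  syn <- synthesize_atac_pairs(cm, ta$fx$pairs, designed, ta$genome,
                               seed = 23L, mapping = mapping,
                               donor_features = ta$peaks)
  expect_equal(nrow(syn), 2L * 10L)
  expect_true(all(syn$frag == syn$src_frag))
  # relocated mates sit 30 kb (within the +/-4 shift) from donor reads
  f1 <- screads:::.assign_to_feature(ta$fx$pairs$chrom,
                                     ta$fx$pairs$pos5_1, ta$peaks)
  f2 <- screads:::.assign_to_feature(ta$fx$pairs$chrom,
                                     ta$fx$pairs$pos5_2, ta$peaks)
  src <- ta$fx$pairs[which(f1 == 3L | f2 == 3L), ]
  expect_true(all(syn$pos5_1 >= min(src$pos5_1) + 30000L - 4L))
  expect_true(all(syn$pos5_1 <= max(src$pos5_1) + 30000L + 4L))
})

test_that("pair-count conservation holds over a whole matrix", {
  ta <- toy_atac()
  cm <- as.matrix(count_reads(ta$fx$pairs, ta$peaks,
                              cells = ta$fx$cells))
  syn <- synthesize_atac_pairs(cm, ta$fx$pairs, ta$peaks, genome = NULL,
                               seed = 24L)
  expect_equal(nrow(syn), sum(ceiling(cm / 2)))
  expect_true(all(abs(syn$pos5_1 -
                        (syn$pos5_1 - syn$shift)) <= 4L))
})

test_that("every synthetic cell gets one unique barcode", {
  pairs <- data.frame(qname = sprintf("p%d", 1:30),
                      chrom = "chr1", pos5_1 = 1:30, len1 = 50L,
                      strand_1 = "+", pos5_2 = 101:130, len2 = 50L,
                      strand_2 = "-",
                      cell = rep(sprintf("s%d", 1:3), each = 10L),
                      stringsAsFactors = FALSE)
  bc <- assign_atac_barcodes(pairs, seed = 25L)
  expect_equal(nrow(bc$whitelist), 3L)
  expect_equal(anyDuplicated(bc$whitelist$barcode), 0L)
  expect_true(all(nchar(bc$whitelist$barcode) == 16L))
  shared <- tapply(bc$pairs$barcode, bc$pairs$cell,
                   function(z) length(unique(z)))
  expect_true(all(shared == 1L))
})
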