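# Synthetic-input generators: toy genome, toy annotation, and toy
# barcoded/UMI-tagged aligned read sets with planted ground truths.  These
# stand in for real sequencing data so every stage of the simulator can be
# exercised and verified without any download.

#' Generate a random toy genome
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome (bp; recycled).
#' @param gc target GC fraction (default 0.42).
#' @param seed integer seed.
#' @return named `DNAStringSet` (chr1, chr2, ...).
#' @export
make_toy_genome <- function(n_chrom = 2L, chrom_len = 1e5, gc = 0.42,
                            seed = 1L) {
  stopifnot(all(chrom_len >= 1))
  set.seed(seed)
  chrom_len <- rep_len(as.integer(chrom_len), n_chrom)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chrom_len, function(len) {
    paste0(sample(names(probs), len, replace = TRUE, prob = probs),
           collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("chr%d", seq_len(n_chrom))
  genome
}

#' Generate a toy gene annotation with planted overlap structure
#'
#' Genes are laid out left to right with gaps; a stated fraction of genes
#' is planted as overlapping pairs (so the expected supergene components
#' are known exactly).  Each gene carries 1-3 transcripts of 1-4 exons
#' within the gene bounds, on a random strand.
#'
#' @param sizes named chromosome lengths.
#' @param n_genes total number of genes.
#' @param overlap_fraction fraction of genes belonging to an overlapping
#'   pair (rounded down to an even count).
#' @param gene_len_range min/max gene length (bp).
#' @param margin distance kept free at chromosome ends (bp).
#' @param seed integer seed.
#' @return list with `genes` (interval table), `exons` (interval table with
#'   `gene_id`, `transcript_id`) and `components` (planted overlap
#'   components as lists of gene ids).
#' @export
make_toy_annotation <- function(sizes, n_genes = 20L, overlap_fraction = 0,
                                gene_len_range = c(600L, 2000L),
                                margin = 400L, seed = 1L) {
  set.seed(seed)
  n_pairs <- floor(n_genes * overlap_fraction / 2)
  n_slots <- n_genes - n_pairs
  chroms <- rep_len(names(sizes), n_slots)[order(rep_len(
    seq_along(sizes), n_slots))]
  genes <- NULL
  exs <- NULL
  components <- list()
  cursor <- stats::setNames(rep(margin, length(sizes)), names(sizes))
  gid <- 0L
  add_gene <- function(ch, start, len, strand) {
    gid <<- gid + 1L
    id <- sprintf("gene_%03d", gid)
    genes <<- rbind(genes, data.frame(chrom = ch, start = start,
                                      end = start + len, strand = strand,
                                      label = "gene", id = id,
                                      stringsAsFactors = FALSE))
    n_tx <- sample.int(3L, 1L)
    for (t in seq_len(n_tx)) {
      n_ex <- sample.int(4L, 1L)
      bounds <- sort(sample(seq.int(0L, len), 2L * n_ex))
      for (e in seq_len(n_ex)) {
        s <- start + bounds[2L * e - 1L]
        en <- start + bounds[2L * e]
        if (en <= s) en <- s + 1L
        exs <<- rbind(exs, data.frame(
          chrom = ch, start = s, end = min(en, start + len),
          strand = strand, label = "exon",
          id = sprintf("%s_t%d_e%d", id, t, e),
          gene_id = id, transcript_id = sprintf("%s_t%d", id, t),
          stringsAsFactors = FALSE))
      }
    }
    id
  }
  slot_is_pair <- rep(FALSE, n_slots)
  if (n_pairs > 0L) slot_is_pair[seq_len(n_pairs)] <- TRUE
  slot_is_pair <- sample(slot_is_pair)
  for (s in seq_len(n_slots)) {
    ch <- chroms[s]
    len <- sample(seq.int(gene_len_range[1L], gene_len_range[2L]), 1L)
    start <- cursor[ch]
    strand <- sample(c("+", "-"), 1L)
    if (start + len + margin > sizes[ch]) next
    id1 <- add_gene(ch, start, len, strand)
    if (slot_is_pair[s]) {
      # partner overlaps the first gene's right half
      len2 <- sample(seq.int(gene_len_range[1L], gene_len_range[2L]), 1L)
      start2 <- start + len %/% 2L
      if (start2 + len2 + margin <= sizes[ch]) {
        id2 <- add_gene(ch, start2, len2, sample(c("+", "-"), 1L))
        components[[length(components) + 1L]] <- c(id1, id2)
        cursor[ch] <- max(start + len, start2 + len2) + 200L
      } else {
        components[[length(components) + 1L]] <- id1
        cursor[ch] <- start + len + 200L
      }
    } else {
      components[[length(components) + 1L]] <- id1
      cursor[ch] <- start + len + 200L
    }
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  exs <- exs[order(exs$chrom, exs$start), , drop = FALSE]
  rownames(genes) <- rownames(exs) <- NULL
  list(genes = genes, exons = exs, components = components)
}

#' Generate toy UMI-tagged scRNA-seq reads with a planted count matrix
#'
#' For each (feature, cell) entry of the planted UMI matrix, that many UMIs
#' are created; each UMI gets a read multiplicity drawn from
#' `reads_per_umi_law` and its reads share a 5' anchor inside the feature.
#' Tabulating the reads with [count_umis()] recovers the planted matrix
#' exactly, and [summarize_reads_per_umi()] recovers the planted law.
#' Sequencing errors are planted at a per-position rate `error_rate`.
#'
#' @param genome named `DNAStringSet`.
#' @param features disjoint interval table (genes or gene/inter-gene
#'   partition) the matrix rows refer to.
#' @param umi_matrix planted feature-by-cell UMI matrix (rownames =
#'   `features$id`), or `NULL` to sample one.
#' @param n_cells number of cells when sampling a matrix.
#' @param mean_umis mean UMIs per (expressed feature, cell) when sampling.
#' @param expressed_fraction fraction of features expressed per cell when
#'   sampling.
#' @param reads_per_umi_law named numeric pmf over read counts per UMI
#'   (default 60/30/10% of 1/2/3 reads).
#' @param read_len read length (bp).
#' @param error_rate scalar or per-position substitution rate.
#' @param cluster_structure optional integer (>1): cells are split into
#'   that many planted clusters expressing disjoint feature subsets.
#' @param seed integer seed.
#' @return list: `reads` (read table with sequences), `umi_matrix`,
#'   `cells`, `law`, `error_rate`, `clusters` (planted labels or NULL).
#' @export
make_toy_scrna_reads <- function(genome, features, umi_matrix = NULL,
                                 n_cells = 20L, mean_umis = 3,
                                 expressed_fraction = 0.7,
                                 reads_per_umi_law =
                                   c("1" = 0.6, "2" = 0.3, "3" = 0.1),
                                 read_len = 90L, error_rate = 0,
                                 cluster_structure = NULL, seed = 1L) {
  set.seed(seed)
  sizes <- chrom_sizes(genome)
  cells <- sprintf("cell_%03d", seq_len(
    if (is.null(umi_matrix)) n_cells else ncol(umi_matrix)))
  clusters <- NULL
  if (is.null(umi_matrix)) {
    p <- nrow(features)
    umi_matrix <- matrix(0L, p, n_cells,
                         dimnames = list(features$id, cells))
    if (is.null(cluster_structure)) {
      for (cidx in seq_len(n_cells)) {
        on <- stats::runif(p) < expressed_fraction
        umi_matrix[on, cidx] <- stats::rpois(sum(on), mean_umis)
      }
    } else {
      kk <- cluster_structure
      clusters <- rep_len(seq_len(kk), n_cells)
      blocks <- split(seq_len(p), rep_len(seq_len(kk), p))
      for (cidx in seq_len(n_cells)) {
        on <- blocks[[clusters[cidx]]]
        umi_matrix[on, cidx] <- stats::rpois(length(on), mean_umis) + 1L
      }
      clusters <- as.character(clusters)
    }
  } else {
    colnames(umi_matrix) <- cells
    rownames(umi_matrix) <- features$id
  }
  law_c <- as.integer(names(reads_per_umi_law))
  recs <- list()
  umi_no <- 0L
  for (i in seq_len(nrow(features))) {
    tot_u <- sum(umi_matrix[i, ])
    if (tot_u == 0L) next
    lo <- features$start[i]
    hi <- features$end[i] - read_len
    if (hi <= lo) hi <- lo + 1L
    cvec <- sample(law_c, tot_u, replace = TRUE, prob = reads_per_umi_law)
    anchor <- sample(seq.int(lo, hi), tot_u, replace = TRUE)
    strand <- sample(c("+", "-"), tot_u, replace = TRUE)
    cell_of_umi <- rep(cells[umi_matrix[i, ] > 0L],
                       umi_matrix[i, umi_matrix[i, ] > 0L])
    umi_ids <- sprintf("UMI%07d", umi_no + seq_len(tot_u))
    umi_no <- umi_no + tot_u
    n_reads <- sum(cvec)
    pos_left <- rep(anchor, cvec)
    strand_r <- rep(strand, cvec)
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = features$chrom[i],
      pos5 = ifelse(strand_r == "-", pos_left + read_len - 1L, pos_left),
      len = read_len, strand = strand_r,
      cell = rep(cell_of_umi, cvec),
      umi = rep(umi_ids, cvec),
      feature = features$id[i],
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, recs)
  if (is.null(reads)) stop("planted matrix produced no reads")
  reads$qname <- sprintf("toy_%07d", seq_len(nrow(reads)))
  left <- .leftmost(reads$pos5, reads$len, reads$strand)
  reads$seq <- extract_sequence(genome, reads$chrom, left,
                                left + reads$len, reads$strand)
  if (any(error_rate > 0)) {
    prof <- error_profile(rep_len(error_rate, read_len))
    reads <- apply_errors(reads, prof)
    reads$qual <- NULL
  }
  list(reads = reads, umi_matrix = umi_matrix, cells = cells,
       law = reads_per_umi_law, error_rate = error_rate,
       clusters = clusters)
}

#' Generate toy paired-end scATAC-seq reads with planted enrichment
#'
#' Fragments are placed either inside planted peaks (with per-base density
#' `enrichment_ratio` times the background) or uniformly elsewhere;
#' fragment sizes follow a clamped normal law.  Mates are 50 nt, in FR
#' orientation.
#'
#' @param genome named `DNAStringSet`.
#' @param peaks interval table of planted peaks.
#' @param n_cells number of cells.
#' @param frags_per_cell mean fragments per cell.
#' @param enrichment_ratio peak/background per-base density ratio (1 = no
#'   enrichment).
#' @param fragment_law numeric `(mean, sd, min)` of the fragment-size law.
#' @param read_len mate length (bp).
#' @param seed integer seed.
#' @return list: `pairs` (pair table), `peaks`, `fragment_law`, `cells`,
#'   `truth_counts` (mate counts per peak/cell by the 5'-assignment rule).
#' @export
make_toy_scatac_reads <- function(genome, peaks, n_cells = 20L,
                                  frags_per_cell = 200L,
                                  enrichment_ratio = 20,
                                  fragment_law = c(mean = 200, sd = 30,
                                                   min = 60),
                                  read_len = 50L, seed = 1L) {
  set.seed(seed)
  sizes <- chrom_sizes(genome)
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  peak_len <- sum(peaks$end - peaks$start)
  genome_len <- sum(sizes)
  w_peak <- peak_len * enrichment_ratio
  w_bg <- genome_len - peak_len
  p_peak <- w_peak / (w_peak + w_bg)
  n_frags <- stats::rpois(n_cells, frags_per_cell)
  tot <- sum(n_frags)
  cell_of <- rep(cells, n_frags)
  in_peak <- stats::runif(tot) < p_peak
  frag <- pmax(round(stats::rnorm(tot, fragment_law[["mean"]],
                                  fragment_law[["sd"]])),
               fragment_law[["min"]])
  chrom <- character(tot)
  left <- integer(tot)
  if (any(in_peak) && nrow(peaks) > 0L) {
    pk <- sample.int(nrow(peaks), sum(in_peak), replace = TRUE,
                     prob = peaks$end - peaks$start)
    chrom[in_peak] <- peaks$chrom[pk]
    span <- pmax(peaks$end[pk] - peaks$start[pk] - 1L, 1L)
    left[in_peak] <- peaks$start[pk] +
      floor(stats::runif(sum(in_peak)) * span)
  }
  if (any(!in_peak)) {
    # background lives on the peak complement so that at
    # enrichment_ratio = 1 the per-base density is flat genome-wide
    bg_iv <- if (nrow(peaks) > 0L) {
      complement_intervals(peaks, sizes)
    } else {
      intervals(names(sizes), 0L, as.integer(sizes))
    }
    iv <- sample.int(nrow(bg_iv), sum(!in_peak), replace = TRUE,
                     prob = bg_iv$end - bg_iv$start)
    chrom[!in_peak] <- bg_iv$chrom[iv]
    span <- pmax(bg_iv$end[iv] - bg_iv$start[iv] - 1L, 1L)
    left[!in_peak] <- bg_iv$start[iv] +
      floor(stats::runif(sum(!in_peak)) * span)
  }
  # clamp so both mates fit
  left <- pmax(left, 0L)
  right_max <- as.integer(sizes[chrom]) - 1L
  frag <- pmin(frag, right_max - left + 1L)
  frag <- pmax(frag, 2L * read_len)
  left <- pmin(left, right_max - frag + 1L)
  pairs <- data.frame(
    qname = sprintf("toyfrag_%07d", seq_len(tot)),
    chrom = chrom,
    pos5_1 = left, len1 = read_len, strand_1 = "+",
    pos5_2 = left + frag - 1L, len2 = read_len, strand_2 = "-",
    cell = cell_of, stringsAsFactors = FALSE)
  pairs$frag <- fragment_size(pairs)
  truth_counts <- if (nrow(peaks) > 0L) {
    count_reads(pairs, peaks, cells = cells)
  } else NULL
  list(pairs = pairs, peaks = peaks, fragment_law = fragment_law,
       cells = cells, truth_counts = truth_counts)
}

#' Write a complete scRNA-seq fixture to a directory
#'
#' Emits genome FASTA, annotation GTF, aligned reads SAM, the planted UMI
#' matrix (MTX) and a truth manifest so file-based entry points can be
#' exercised end to end.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param ... forwarded to [make_toy_scrna_reads()].
#' @return (invisibly) list of paths plus the in-memory truth bundle.
#' @export
write_rna_fixture <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_toy_genome(n_chrom = 2L, chrom_len = 6e4, seed = seed)
  sizes <- chrom_sizes(genome)
  ann <- make_toy_annotation(sizes, n_genes = 12L, overlap_fraction = 0.3,
                             seed = seed)
  fx <- make_toy_scrna_reads(genome, ann$genes, seed = seed, ...)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                sam = file.path(dir, "reads.sam"),
                mtx_dir = file.path(dir, "umi_matrix"))
  Biostrings::writeXStringSet(genome, paths$fasta)
  write_gtf(ann$genes, ann$exons, paths$gtf)
  write_alignments(paths$sam, sizes, reads = fx$reads)
  write_matrix(Matrix::Matrix(fx$umi_matrix, sparse = TRUE),
               paths$mtx_dir)
  invisible(c(paths, list(genome = genome, annotation = ann, fixture = fx)))
}
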