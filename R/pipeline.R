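# End-to-end pipeline drivers: read/segment/count/fit/sample/synthesize/
# inject-errors/write, for scRNA-seq and scATAC-seq.  These are the
# programmatic equivalents of the command-line entry points; every random
# stage runs inside one seeded RNG stream so identical configurations give
# byte-identical outputs.

.as_genome <- function(genome) {
  if (is.character(genome)) read_genome(genome) else genome
}

.write_manifest <- function(path, params) {
  params$package_version <- as.character(utils::packageVersion("screads"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

.fastq_name <- function(qname, barcode, umi = NULL) {
  if (is.null(umi)) paste(qname, barcode, sep = ":")
  else paste(qname, barcode, umi, sep = ":")
}

#' Simulate synthetic scRNA-seq reads with ground-truth UMI matrices
#'
#' Full scRNA-seq workflow: merge overlapping genes into non-overlapping
#' features, take inter-genes as their complement, build gene- and
#' inter-gene-by-cell UMI matrices, fit the per-cluster NB copula count
#' model to each, sample synthetic matrices at the requested cell number
#' and depth, generate reads 2 by resampling real reads (or uniformly on
#' collapsed transcripts in transcriptome mode), inject substitution errors
#' estimated from the real reads, and pair every read 2 with a read 1
#' carrying the cell barcode and UMI.
#'
#' @param reads aligned read table (or SAM/BAM path) with barcode and UMI.
#' @param genes gene interval table, or a GTF path.
#' @param genome named `DNAStringSet` or FASTA path.
#' @param outdir output directory; `NULL` skips file output.
#' @param n_cells synthetic cell number (default: as many as real cells).
#' @param depth_factor sequencing-depth factor (default 1).
#' @param labels optional real-cell cluster labels (else Louvain).
#' @param read_len read-2 length (default 90).
#' @param barcode_len,umi_len read-1 composition (defaults 16 + 10 = 26).
#' @param shift_range maximum absolute 5' shift (default 4).
#' @param transcriptome_mode generate reads from collapsed transcripts.
#' @param exons exon interval table (required in transcriptome mode when
#'   `genes` is not a GTF path).
#' @param inject_errors estimate an error profile from the real reads and
#'   apply it (requires a `seq` column on the real reads).
#' @param copula_top_j copula feature cap per cluster (default 500).
#' @param seed master seed.
#' @return list with the synthetic read ledger, read-1 records, synthetic
#'   matrices, feature tables, models, whitelist and output paths.
#' @export
simulate_rna <- function(reads, genes, genome, outdir = NULL,
                         n_cells = NULL, depth_factor = 1, labels = NULL,
                         read_len = 90L, barcode_len = 16L, umi_len = 10L,
                         shift_range = 4L, transcriptome_mode = FALSE,
                         exons = NULL, inject_errors = TRUE,
                         copula_top_j = 500L, seed = 1L) {
  set.seed(seed)
  genome <- .as_genome(genome)
  sizes <- chrom_sizes(genome)
  if (is.character(reads)) reads <- read_alignments(reads)
  if (is.character(genes)) {
    ann <- read_gtf(genes)
    genes <- ann$genes
    if (is.null(exons)) exons <- ann$exons
  }
  if (transcriptome_mode && is.null(exons)) {
    stop("transcriptome mode requires exon annotation")
  }
  features <- merge_overlapping_genes(genes)
  intergenes <- complement_intervals(features, sizes, label = "intergene")
  intergenes$id <- sprintf("intergene_%d", seq_len(nrow(intergenes)))
  cells <- sort(unique(reads$cell))
  gene_mat <- count_umis(reads, features, cells = cells)
  inter_mat <- count_umis(reads, intergenes, cells = cells)
  if (is.null(labels)) labels <- cluster_cells(as.matrix(gene_mat))
  model_gene <- fit_count_model(gene_mat, labels,
                                copula_top_j = copula_top_j)
  model_inter <- fit_count_model(inter_mat, labels,
                                 copula_top_j = copula_top_j)
  if (is.null(n_cells)) n_cells <- length(cells)
  assignment <- sample(model_gene$clusters, n_cells, replace = TRUE,
                       prob = model_gene$pi)
  synth_gene <- sample_counts(model_gene, n_cells, depth_factor,
                              cluster_assignment = assignment)
  synth_inter <- sample_counts(model_inter, n_cells, depth_factor,
                               cluster_assignment = assignment)
  rpu_gene <- summarize_reads_per_umi(reads, features)
  rpu_inter <- summarize_reads_per_umi(reads, intergenes)
  if (transcriptome_mode) {
    ex2 <- exons
    member_map <- rep(features$id, features$n_members)
    names(member_map) <- unlist(strsplit(features$members, ","))
    ex2$gene_id <- unname(member_map[ex2$gene_id])
    # a supergene can mix strands; collapse it on the forward strand
    mixed <- tapply(ex2$strand, ex2$gene_id,
                    function(s) length(unique(s[s %in% c("+", "-")])) > 1L)
    ex2$strand[ex2$gene_id %in% names(mixed)[mixed]] <- "+"
    collapsed <- collapse_transcriptome(ex2, genome)
    ledger <- synthesize_rna_reads_transcriptome(
      synth_gene, rpu_gene, collapsed, read_len = read_len)
    ledger$source <- "transcriptome"
  } else {
    ledger_g <- synthesize_rna_reads(synth_gene, rpu_gene, reads, features,
                                     genome, read_len = read_len,
                                     shift_range = shift_range)
    ledger_i <- synthesize_rna_reads(synth_inter, rpu_inter, reads,
                                     intergenes, genome,
                                     read_len = read_len,
                                     shift_range = shift_range)
    ledger <- rbind(ledger_g, ledger_i)
    ledger$qname <- sprintf("rna_%07d", seq_len(nrow(ledger)))
    ledger$source <- "genome"
  }
  profile <- NULL
  if (inject_errors && "seq" %in% names(reads)) {
    profile <- estimate_error_profile(reads, genome)
    ledger <- apply_errors(ledger, profile)
  } else {
    ledger$qual <- strrep("F", nchar(ledger$seq))
  }
  r1 <- synthesize_read1(ledger, barcode_len = barcode_len,
                         umi_len = umi_len)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    nm <- .fastq_name(ledger$qname, r1$records$barcode, r1$records$umi)
    paths <- list(
      r1 = file.path(outdir, "reads_R1.fastq"),
      r2 = file.path(outdir, "reads_R2.fastq"),
      gene_mtx = file.path(outdir, "gene_umi_matrix"),
      intergene_mtx = file.path(outdir, "intergene_umi_matrix"),
      whitelist = file.path(outdir, "barcode_whitelist.txt"),
      sam = file.path(outdir, "synthetic_reads.sam"),
      manifest = file.path(outdir, "manifest.json"))
    write_fastq(data.frame(name = nm, seq = r1$records$seq,
                           qual = r1$records$qual), paths$r1)
    write_fastq(data.frame(name = nm, seq = ledger$seq,
                           qual = ledger$qual), paths$r2)
    write_matrix(Matrix::Matrix(synth_gene, sparse = TRUE), paths$gene_mtx)
    write_matrix(Matrix::Matrix(synth_inter, sparse = TRUE),
                 paths$intergene_mtx)
    writeLines(r1$whitelist$barcode, paths$whitelist)
    if (!transcriptome_mode) {
      sam_reads <- ledger
      sam_reads$cell <- r1$records$barcode
      sam_reads$umi <- r1$records$umi
      write_alignments(paths$sam, sizes, reads = sam_reads)
    }
    .write_manifest(paths$manifest, list(
      mode = "rna", n_cells = n_cells, depth_factor = depth_factor,
      read_len = read_len, barcode_len = barcode_len, umi_len = umi_len,
      shift_range = shift_range, transcriptome_mode = transcriptome_mode,
      seed = seed))
  }
  list(ledger = ledger, read1 = r1$records, whitelist = r1$whitelist,
       synth_gene = synth_gene, synth_intergene = synth_inter,
       genes = features, intergenes = intergenes,
       model_gene = model_gene, model_intergene = model_inter,
       labels = labels, error_profile = profile, paths = paths)
}

#' Simulate synthetic scATAC-seq read pairs with ground-truth regions
#'
#' Mimic mode trains on trustworthy peaks/non-peaks (user-supplied or
#' called by the internal coverage-window fallback), converts gray areas to
#' ground-truth non-peaks via donor-row masking, and resamples real pairs
#' per feature.  Designed-truth mode (`designed_peaks` given) maps each
#' designed region to a length-similar trustworthy donor, relocates the
#' donor's reads by the signed feature distance, and emits the designed
#' regions as the ground-truth peak set.
#'
#' @param pairs real pair table, or a SAM/BAM path of name-paired reads.
#' @param genome named `DNAStringSet` or FASTA path.
#' @param peaks,nonpeaks trustworthy region interval tables; both `NULL`
#'   triggers [call_regions_by_coverage()] (set `fallback = FALSE` to
#'   error instead).
#' @param designed_peaks optional user-designed ground-truth peak table
#'   (overlapping entries are merged with a warning).
#' @param outdir output directory; `NULL` skips file output.
#' @param n_cells,depth_factor,labels,read_len,shift_range,barcode_len,seed
#'   as in [simulate_rna()] (`read_len` default 50).
#' @param profile optional `error_profile` to inject substitution errors
#'   into both mates (estimated from the real mates when they carry
#'   sequences and `profile` is `NULL`).
#' @param fallback allow the internal region caller when no trustworthy
#'   regions are given (default TRUE).
#' @param copula_top_j copula feature cap per cluster.
#' @return list with the synthetic pair table, ground-truth region tables,
#'   synthetic matrices, whitelist, models and output paths.
#' @export
simulate_atac <- function(pairs, genome, peaks = NULL, nonpeaks = NULL,
                          designed_peaks = NULL, outdir = NULL,
                          n_cells = NULL, depth_factor = 1, labels = NULL,
                          read_len = 50L, shift_range = 4L,
                          barcode_len = 16L, profile = NULL,
                          fallback = TRUE, copula_top_j = 500L,
                          seed = 1L) {
  set.seed(seed)
  genome <- .as_genome(genome)
  sizes <- chrom_sizes(genome)
  if (is.character(pairs)) pairs <- read_alignments(pairs, paired = TRUE)$pairs
  if (is.null(peaks) || is.null(nonpeaks)) {
    if (!fallback) stop("no trustworthy regions supplied and fallback disabled")
    mates <- data.frame(chrom = c(pairs$chrom, pairs$chrom),
                        pos5 = c(pairs$pos5_1, pairs$pos5_2),
                        stringsAsFactors = FALSE)
    called <- call_regions_by_coverage(mates, sizes)
    peaks <- called$peaks
    nonpeaks <- called$nonpeaks
  }
  partition <- build_atac_partition(peaks, nonpeaks, sizes)
  peaks <- partition$peaks
  nonpeaks <- partition$nonpeaks
  cells <- sort(unique(pairs$cell))
  peak_mat <- count_reads(pairs, peaks, cells = cells)
  nonpeak_mat <- count_reads(pairs, nonpeaks, cells = cells)
  if (is.null(labels)) labels <- cluster_cells(as.matrix(peak_mat))
  if (is.null(n_cells)) n_cells <- length(cells)
  if (is.null(profile) && "seq1" %in% names(pairs)) {
    mates1 <- data.frame(chrom = pairs$chrom, pos5 = pairs$pos5_1,
                         len = pairs$len1, strand = pairs$strand_1,
                         seq = pairs$seq1, stringsAsFactors = FALSE)
    profile <- estimate_error_profile(mates1, genome)
  }
  if (!is.null(designed_peaks)) {
    merged <- merge_overlapping_genes(designed_peaks)
    if (nrow(merged) < nrow(designed_peaks)) {
      warning("overlapping designed peaks merged: ",
              nrow(designed_peaks), " -> ", nrow(merged))
      designed_peaks <- intervals(merged$chrom, merged$start, merged$end,
                                  label = "gt_peak",
                                  id = sprintf("gt_peak_%d",
                                               seq_len(nrow(merged))))
    }
    gt_nonpeaks <- complement_intervals(designed_peaks, sizes,
                                        label = "gt_nonpeak")
    gt_nonpeaks$id <- sprintf("gt_nonpeak_%d", seq_len(nrow(gt_nonpeaks)))
    mapped_p <- map_designed_counts(designed_peaks, peaks, peak_mat,
                                    mode = "peak")
    mapped_np <- map_designed_counts(gt_nonpeaks, nonpeaks, nonpeak_mat,
                                     mode = "nonpeak")
    model_peak <- fit_count_model(mapped_p$counts, labels,
                                  copula_top_j = copula_top_j)
    model_nonpeak <- fit_count_model(mapped_np$counts, labels,
                                     copula_top_j = copula_top_j)
    assignment <- sample(model_peak$clusters, n_cells, replace = TRUE,
                         prob = model_peak$pi)
    synth_peak <- sample_counts(model_peak, n_cells, depth_factor,
                                cluster_assignment = assignment)
    synth_nonpeak <- sample_counts(model_nonpeak, n_cells, depth_factor,
                                   cluster_assignment = assignment)
    syn_pairs <- rbind(
      synthesize_atac_pairs(synth_peak, pairs, designed_peaks, genome,
                            read_len = read_len,
                            shift_range = shift_range,
                            mapping = mapped_p$mapping,
                            donor_features = peaks),
      synthesize_atac_pairs(synth_nonpeak, pairs, gt_nonpeaks, genome,
                            read_len = read_len,
                            shift_range = shift_range,
                            mapping = mapped_np$mapping,
                            donor_features = nonpeaks))
    gt_peaks_out <- designed_peaks
    gt_nonpeaks_out <- gt_nonpeaks
    synth_gray <- NULL
  } else {
    model_peak <- fit_count_model(peak_mat, labels,
                                  copula_top_j = copula_top_j)
    model_nonpeak <- fit_count_model(nonpeak_mat, labels,
                                     copula_top_j = copula_top_j)
    assignment <- sample(model_peak$clusters, n_cells, replace = TRUE,
                         prob = model_peak$pi)
    synth_peak <- sample_counts(model_peak, n_cells, depth_factor,
                                cluster_assignment = assignment)
    synth_nonpeak <- sample_counts(model_nonpeak, n_cells, depth_factor,
                                   cluster_assignment = assignment)
    synth_gray <- build_gray_counts(partition$gray, nonpeaks,
                                    synth_nonpeak)
    syn_pairs <- rbind(
      synthesize_atac_pairs(synth_peak, pairs, peaks, genome,
                            read_len = read_len,
                            shift_range = shift_range),
      synthesize_atac_pairs(synth_nonpeak, pairs, nonpeaks, genome,
                            read_len = read_len,
                            shift_range = shift_range),
      synthesize_atac_pairs(synth_gray, pairs, partition$gray, genome,
                            read_len = read_len,
                            shift_range = shift_range))
    gt_peaks_out <- peaks
    gt_peaks_out$label <- "gt_peak"
    gt_nonpeaks_out <- rbind(nonpeaks, partition$gray)
    gt_nonpeaks_out$label <- "gt_nonpeak"
    gt_nonpeaks_out <-
      gt_nonpeaks_out[order(gt_nonpeaks_out$chrom, gt_nonpeaks_out$start),
                      , drop = FALSE]
  }
  if (!is.null(profile) && "seq1" %in% names(syn_pairs)) {
    # substitution errors are introduced separately for the two mates
    m1 <- apply_errors(data.frame(seq = syn_pairs$seq1), profile)
    m2 <- apply_errors(data.frame(seq = syn_pairs$seq2), profile)
    syn_pairs$seq1 <- m1$seq
    syn_pairs$qual1 <- m1$qual
    syn_pairs$seq2 <- m2$seq
    syn_pairs$qual2 <- m2$qual
  } else if ("seq1" %in% names(syn_pairs)) {
    syn_pairs$qual1 <- strrep("F", nchar(syn_pairs$seq1))
    syn_pairs$qual2 <- strrep("F", nchar(syn_pairs$seq2))
  }
  bc <- assign_atac_barcodes(syn_pairs, barcode_len = barcode_len)
  syn_pairs <- bc$pairs
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    nm <- .fastq_name(syn_pairs$qname, syn_pairs$barcode)
    paths <- list(
      r1 = file.path(outdir, "reads_R1.fastq"),
      r2 = file.path(outdir, "reads_R2.fastq"),
      peak_mtx = file.path(outdir, "peak_matrix"),
      nonpeak_mtx = file.path(outdir, "nonpeak_matrix"),
      gt_peaks = file.path(outdir, "ground_truth_peaks.bed"),
      gt_nonpeaks = file.path(outdir, "ground_truth_nonpeaks.bed"),
      whitelist = file.path(outdir, "barcode_whitelist.txt"),
      sam = file.path(outdir, "synthetic_pairs.sam"),
      manifest = file.path(outdir, "manifest.json"))
    write_fastq(data.frame(name = nm, seq = syn_pairs$seq1,
                           qual = syn_pairs$qual1), paths$r1)
    write_fastq(data.frame(name = nm, seq = syn_pairs$seq2,
                           qual = syn_pairs$qual2), paths$r2)
    write_matrix(Matrix::Matrix(synth_peak, sparse = TRUE),
                 paths$peak_mtx)
    write_matrix(Matrix::Matrix(synth_nonpeak, sparse = TRUE),
                 paths$nonpeak_mtx)
    write_bed(gt_peaks_out, paths$gt_peaks)
    write_bed(gt_nonpeaks_out, paths$gt_nonpeaks)
    writeLines(bc$whitelist$barcode, paths$whitelist)
    sam_pairs <- syn_pairs
    sam_pairs$cell <- syn_pairs$barcode
    write_alignments(paths$sam, sizes, pairs = sam_pairs)
    .write_manifest(paths$manifest, list(
      mode = if (is.null(designed_peaks)) "atac-mimic" else "atac-designed",
      n_cells = n_cells, depth_factor = depth_factor,
      read_len = read_len, barcode_len = barcode_len,
      shift_range = shift_range, seed = seed))
  }
  list(pairs = syn_pairs, whitelist = bc$whitelist,
       synth_peak = synth_peak, synth_nonpeak = synth_nonpeak,
       synth_gray = synth_gray,
       gt_peaks = gt_peaks_out, gt_nonpeaks = gt_nonpeaks_out,
       trustworthy_peaks = peaks, trustworthy_nonpeaks = nonpeaks,
       partition = partition, model_peak = model_peak,
       model_nonpeak = model_nonpeak, labels = labels, paths = paths)
}
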