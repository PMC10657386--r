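# Genome partitioning: genes/inter-genes (scRNA-seq) and
# peaks/non-peaks/gray areas (scATAC-seq).
#
# All intervals are 0-based half-open [start, end) on the forward strand of a
# named chromosome, the BED/SAM native convention.  GTF input (1-based closed)
# is converted at the I/O boundary (see read_gtf).

#' Construct a genomic interval table
#'
#' The package-wide interval container: a plain `data.frame` with columns
#' `chrom`, `start`, `end` (0-based half-open), `strand`, `label`, `id`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand one of `"+"`, `"-"`, `"*"` per interval (recycled).
#' @param label role tag, e.g. `"gene"`, `"peak"`, `"nonpeak"`, `"gray"`.
#' @param id stable identifiers; autogenerated from label + rank if missing.
#' @return a `data.frame` of intervals sorted by (chrom, start).
#' @export
intervals <- function(chrom, start, end, strand = "*", label = NA_character_,
                      id = NULL) {
  n <- length(chrom)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), label = character(),
                      id = character(), stringsAsFactors = FALSE))
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) {
    stop("invalid interval: start must be < end (0-based half-open)")
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = rep_len(as.character(strand), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  df$id <- if (is.null(id)) {
    sprintf("%s_%d", ifelse(is.na(df$label), "iv", df$label), seq_len(n))
  } else {
    as.character(id)
  }
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

.empty_intervals <- function() intervals(character(), integer(), integer())

# internal converters to/from GRanges (1-based closed)
.gi2gr <- function(df) {
  st <- if (is.null(df$strand)) rep("*", nrow(df)) else df$strand
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(st %in% c("+", "-"), st, "*")
  )
}

.gr2gi <- function(gr, label = NA_character_, id = NULL) {
  intervals(chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1L,
            end = GenomicRanges::end(gr),
            strand = as.character(GenomicRanges::strand(gr)),
            label = label, id = id)
}

.check_bounds <- function(df, chrom_sizes) {
  unknown <- setdiff(df$chrom, names(chrom_sizes))
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  if (any(df$end > chrom_sizes[df$chrom])) {
    stop("interval out of chromosome bounds")
  }
  invisible(df)
}

#' Aggregate overlapping genes into non-overlapping features
#'
#' Genes whose intervals overlap (or nest) are merged into "supergenes" that
#' span the union of each connected overlap component, so a read can never be
#' double-counted by two overlapping genes.  Member gene ids are retained in
#' a `members` column (comma-separated).
#'
#' @param genes interval table with gene `id`s; may overlap.
#' @return non-overlapping interval table labelled `gene`, sorted by
#'   (chrom, start), with a `members` column listing constituent gene ids
#'   and `n_members` counting them.
#' @export
merge_overlapping_genes <- function(genes) {
  if (nrow(genes) == 0L) {
    out <- .empty_intervals()
    out$members <- character()
    out$n_members <- integer()
    return(out)
  }
  if (any(genes$start >= genes$end)) stop("invalid interval: start >= end")
  gr <- .gi2gr(genes)
  GenomicRanges::strand(gr) <- "*"   # genes on either strand can share reads
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  members <- vapply(revmap, function(ix) {
    paste(sort(genes$id[ix]), collapse = ",")
  }, character(1))
  nm <- lengths(revmap)
  out <- .gr2gi(red, label = "gene")
  out$id <- ifelse(nm > 1L, sprintf("supergene_%d", seq_along(nm)),
                   vapply(revmap, function(ix) genes$id[ix[1L]], character(1)))
  out$members <- members
  out$n_members <- nm
  out$strand <- "*"
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Complement of a disjoint feature set within chromosomes
#'
#' Returns the maximal gaps between features and at chromosome ends, so that
#' features plus complement tile every chromosome in `chrom_sizes` exactly.
#'
#' @param features disjoint interval table.
#' @param chrom_sizes named integer vector, chromosome -> length (bp).
#' @param label label for the returned intervals.
#' @return interval table of gaps (zero-length gaps omitted).
#' @export
complement_intervals <- function(features, chrom_sizes,
                                 label = "complement") {
  .check_bounds(features, chrom_sizes)
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- unname(chrom_sizes[[ch]])
    f <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0L) {
      return(data.frame(chrom = ch, start = 0L, end = as.integer(len),
                        stringsAsFactors = FALSE))
    }
    f <- f[order(f$start), , drop = FALSE]
    if (any(f$start[-1L] < f$end[-nrow(f)])) {
      stop("features must be disjoint within a chromosome: ", ch)
    }
    bounds_start <- c(0L, f$end)
    bounds_end <- c(f$start, as.integer(len))
    keep <- bounds_start < bounds_end
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = bounds_start[keep], end = bounds_end[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_intervals())
  intervals(out$chrom, out$start, out$end, strand = "*", label = label)
}

#' Build the peak / non-peak / gray-area partition for scATAC-seq
#'
#' Gray areas are the regions that cannot be confidently classified as open
#' (peak) or closed (non-peak) chromatin: the complement of the union of the
#' trustworthy peaks and non-peaks.
#'
#' @param peaks,nonpeaks disjoint interval tables (mutually disjoint too).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return a list of class `genome_partition` with elements `peaks`,
#'   `nonpeaks`, `gray`, `chrom_sizes`; the three sets tile every chromosome.
#' @export
build_atac_partition <- function(peaks, nonpeaks, chrom_sizes) {
  .check_bounds(peaks, chrom_sizes)
  .check_bounds(nonpeaks, chrom_sizes)
  hits <- GenomicRanges::findOverlaps(.gi2gr(peaks), .gi2gr(nonpeaks),
                                      ignore.strand = TRUE)
  if (length(hits) > 0L) {
    off <- sprintf("%s vs %s",
                   peaks$id[S4Vectors::queryHits(hits)],
                   nonpeaks$id[S4Vectors::subjectHits(hits)])
    stop("conflicting regions: peak/non-peak overlap for ",
         paste(utils::head(off, 10L), collapse = "; "))
  }
  peaks$label <- "peak"
  nonpeaks$label <- "nonpeak"
  both <- rbind(peaks[, c("chrom", "start", "end")],
                nonpeaks[, c("chrom", "start", "end")])
  both <- intervals(both$chrom, both$start, both$end)
  gray <- complement_intervals(both, chrom_sizes, label = "gray")
  gray$id <- sprintf("gray_%d", seq_len(nrow(gray)))
  structure(list(peaks = peaks, nonpeaks = nonpeaks, gray = gray,
                 chrom_sizes = chrom_sizes),
            class = "genome_partition")
}

#' @exportS3Method print genome_partition
#' @export
print.genome_partition <- function(x, ...) {
  cat("genome_partition:",
      nrow(x$peaks), "peaks,",
      nrow(x$nonpeaks), "non-peaks,",
      nrow(x$gray), "gray areas on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Select candidate regions covered at least half by reference regions
#'
#' A candidate is kept when the total length covered by the union of the
#' reference regions is at least half the candidate's own length — the rule
#' used to promote externally supplied possible peaks (or non-peaks) to
#' trustworthy status.
#'
#' @param candidates,reference_regions interval tables.
#' @return the selected subset of `candidates`.
#' @export
select_trustworthy_by_overlap <- function(candidates, reference_regions) {
  if (nrow(candidates) == 0L) return(candidates)
  if (nrow(reference_regions) == 0L) return(candidates[0L, , drop = FALSE])
  cand <- .gi2gr(candidates)
  ref <- GenomicRanges::reduce(.gi2gr(reference_regions),
                               ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(cand, ref, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(cand[S4Vectors::queryHits(hits)],
                                  ref[S4Vectors::subjectHits(hits)])
  covered <- rep(0L, nrow(candidates))
  if (length(hits)) {
    tot <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(tot))] <- as.integer(tot)
  }
  len <- candidates$end - candidates$start
  candidates[covered * 2L >= len, , drop = FALSE]
}

#' Call trustworthy peaks and non-peaks from read coverage
#'
#' Lightweight fallback region caller used when no trustworthy peak /
#' non-peak annotation is supplied.  The genome is tiled into fixed windows;
#' window counts of read 5' positions are compared against a Poisson
#' background (rate = genome-wide mean count per window).  Two rules are
#' applied: a stringent rule (upper-tail probability `stringent_q`) defines
#' trustworthy peaks; the complement of the relaxed-rule (`relaxed_q`) peaks
#' defines trustworthy non-peaks, so peaks and non-peaks can never overlap.
#'
#' @param reads data.frame of aligned reads with columns `chrom`, `pos5`.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param stringent_q,relaxed_q q-value thresholds: per-window Poisson
#'   upper-tail p-values are BH-adjusted and a window is enriched under a
#'   rule when its q-value is at most the threshold.  Requires
#'   `stringent_q <= relaxed_q` (the stringent rule is the smaller q).
#' @param window window size in bp.
#' @return list with interval tables `peaks` and `nonpeaks`.
#' @export
call_regions_by_coverage <- function(reads, chrom_sizes,
                                     stringent_q = 0.01, relaxed_q = 0.1,
                                     window = 500L) {
  if (nrow(reads) == 0L) stop("empty read set")
  if (stringent_q > relaxed_q) {
    stop("stringent_q must be <= relaxed_q (more stringent rule)")
  }
  if (window < 1L) stop("window must be >= 1")
  window <- as.integer(window)
  counts_per_chrom <- lapply(names(chrom_sizes), function(ch) {
    len <- unname(chrom_sizes[[ch]])
    nw <- as.integer(ceiling(len / window))
    cnt <- integer(nw)
    p <- reads$pos5[reads$chrom == ch]
    if (length(p)) {
      tb <- table(pmin(p %/% window + 1L, nw))
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    cnt
  })
  names(counts_per_chrom) <- names(chrom_sizes)
  lambda <- sum(vapply(counts_per_chrom, sum, 0)) /
    sum(lengths(counts_per_chrom))
  # per-window Poisson upper-tail p-values, BH-adjusted to q-values
  allq <- stats::p.adjust(
    stats::ppois(unlist(counts_per_chrom) - 1L, lambda,
                 lower.tail = FALSE),
    method = "BH")
  q_per_chrom <- split(allq, rep(seq_along(counts_per_chrom),
                                 lengths(counts_per_chrom)))
  names(q_per_chrom) <- names(counts_per_chrom)
  peaks_for <- function(qthr) {
    out <- lapply(names(chrom_sizes), function(ch) {
      hot <- which(q_per_chrom[[ch]] <= qthr)
      if (!length(hot)) return(NULL)
      len <- unname(chrom_sizes[[ch]])
      data.frame(chrom = ch, start = (hot - 1L) * window,
                 end = pmin(hot * window, as.integer(len)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out) || nrow(out) == 0L) return(.empty_intervals())
    gr <- GenomicRanges::reduce(.gi2gr(out))
    .gr2gi(gr, label = "peak")
  }
  stringent_peaks <- peaks_for(stringent_q)
  relaxed_peaks <- peaks_for(relaxed_q)
  nonpeaks <- complement_intervals(relaxed_peaks, chrom_sizes,
                                   label = "nonpeak")
  stringent_peaks$id <- sprintf("peak_%d", seq_len(nrow(stringent_peaks)))
  nonpeaks$id <- sprintf("nonpeak_%d", seq_len(nrow(nonpeaks)))
  list(peaks = stringent_peaks, nonpeaks = nonpeaks)
}

#' Design ground-truth peaks downstream of transcription start sites
#'
#' Each designed peak spans `[TSS, TSS + LEN - 1]` in 1-based closed
#' coordinates (equivalently `[TSS0, TSS0 + LEN)` internally), with `LEN`
#' drawn discrete-uniformly from `min_len..max_len`; overlapping designed
#' peaks are merged so the final truth set is non-overlapping.
#'
#' @param tss data.frame with columns `chrom`, `pos` (0-based TSS position)
#'   and optionally `strand` (unused for peak placement).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param min_len,max_len peak length bounds in bp (defaults 250 and 550).
#' @param seed integer seed; the design is deterministic given the seed.
#' @return interval table labelled `gt_peak`.
#' @export
design_tss_peaks <- function(tss, chrom_sizes, min_len = 250L,
                             max_len = 550L, seed = 1L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (any(tss$pos < 0L) || any(tss$pos >= chrom_sizes[tss$chrom])) {
    stop("TSS outside chromosome bounds")
  }
  set.seed(seed)
  len <- if (min_len == max_len) {
    rep(as.integer(min_len), nrow(tss))
  } else {
    sample(seq.int(min_len, max_len), nrow(tss), replace = TRUE)
  }
  end <- pmin(tss$pos + len, as.integer(chrom_sizes[tss$chrom]))
  raw <- intervals(tss$chrom, tss$pos, end, label = "gt_peak")
  merged <- GenomicRanges::reduce(.gi2gr(raw), ignore.strand = TRUE)
  out <- .gr2gi(merged, label = "gt_peak")
  out$id <- sprintf("gt_peak_%d", seq_len(nrow(out)))
  out
}
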