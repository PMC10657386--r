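# Per-read-position substitution error model.
#
# Position i runs 5'->3' along the sequencing read (read orientation, not
# genomic coordinates).  The profile stores, per position, the total error
# rate p_i and the distribution of the substituting nucleotide, conditional
# on the reference base (with an aggregate fallback for sparse cells).
# Injection draws a Bernoulli(p_i) indicator per base; substituted bases get
# Phred quality 24 ('9'), untouched bases quality 37 ('F').

.BASES <- c("A", "C", "G", "T")
# the three alternative bases for each reference base, alphabetical order
.ALTS <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Construct a substitution error profile
#'
#' @param p numeric vector of per-position total error rates in `[0, 1]`.
#' @param alt_cond optional array `length(p) x 4 x 3`: per position and
#'   reference base (A,C,G,T), the probabilities of the three alternative
#'   bases given an error (rows sum to 1).  Defaults to uniform 1/3.
#' @param n_cond optional observation-count matrix `length(p) x 4` backing
#'   `alt_cond`; cells with fewer than `min_obs` observations fall back to
#'   the positional aggregate at injection time.
#' @param alt_agg optional matrix `length(p) x 3` of aggregate alternative
#'   probabilities per position.
#' @param n optional total observations per position.
#' @param min_obs sparsity threshold for the conditional cells (default 50).
#' @return object of class `error_profile`.
#' @export
error_profile <- function(p, alt_cond = NULL, n_cond = NULL,
                          alt_agg = NULL, n = NULL, min_obs = 50L) {
  L <- length(p)
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(alt_cond)) {
    alt_cond <- array(1 / 3, dim = c(L, 4L, 3L))
  }
  if (is.null(alt_agg)) alt_agg <- matrix(1 / 3, L, 3L)
  if (is.null(n_cond)) n_cond <- matrix(0L, L, 4L)
  if (is.null(n)) n <- rep(0L, L)
  structure(list(p = p, alt_cond = alt_cond, n_cond = n_cond,
                 alt_agg = alt_agg, n = n, min_obs = min_obs),
            class = "error_profile")
}

#' @exportS3Method print error_profile
#' @export
print.error_profile <- function(x, ...) {
  cat("substitution error profile over", length(x$p), "read positions\n")
  cat("  mean error rate:", signif(mean(x$p), 4),
      " max:", signif(max(x$p), 4), "\n")
  invisible(x)
}

# read-oriented reference sequences for a read table
.expected_ref <- function(reads, genome) {
  left <- .leftmost(reads$pos5, reads$len, reads$strand)
  extract_sequence(genome, reads$chrom, left, left + reads$len,
                   reads$strand)
}

#' Estimate the per-position substitution error profile from aligned reads
#'
#' Each read's sequence is compared base-by-base with the (strand-aware)
#' reference sequence at its alignment; mismatches are tabulated per read
#' position and reference base.  Positions never observed get rate 0.
#'
#' @param reads read data.frame with `chrom`, `pos5`, `len`, `strand`,
#'   `seq` (read-oriented).
#' @param genome named `DNAStringSet`.
#' @param min_obs sparsity threshold for conditional alternative-base cells.
#' @return an `error_profile`.
#' @export
estimate_error_profile <- function(reads, genome, min_obs = 50L) {
  if (nrow(reads) == 0L) stop("no aligned reads")
  ref <- .expected_ref(reads, genome)
  L <- max(reads$len)
  obs <- matrix(0L, L, 4L, dimnames = list(NULL, .BASES))
  mism <- array(0L, dim = c(L, 4L, 3L))
  for (len in unique(reads$len)) {
    ix <- which(reads$len == len)
    rm_ <- matrix(unlist(strsplit(ref[ix], "")), ncol = len, byrow = TRUE)
    sm_ <- matrix(unlist(strsplit(reads$seq[ix], "")), ncol = len,
                  byrow = TRUE)
    for (b in seq_along(.BASES)) {
      isb <- rm_ == .BASES[b]
      obs[seq_len(len), b] <- obs[seq_len(len), b] + colSums(isb)
      for (a in 1:3) {
        hit <- isb & sm_ == .ALTS[[.BASES[b]]][a]
        mism[seq_len(len), b, a] <- mism[seq_len(len), b, a] + colSums(hit)
      }
    }
  }
  n <- rowSums(obs)
  tot_mism_pos <- apply(mism, 1L, sum)
  p <- ifelse(n > 0L, tot_mism_pos / n, 0)
  # conditional alternative probabilities (given an error at pos, ref base)
  alt_cond <- array(1 / 3, dim = c(L, 4L, 3L))
  for (b in 1:4) {
    mb <- matrix(mism[, b, ], nrow = L)
    tot <- rowSums(mb)
    nz <- tot > 0L
    if (any(nz)) alt_cond[nz, b, ] <- mb[nz, , drop = FALSE] / tot[nz]
  }
  agg <- apply(mism, c(1L, 3L), sum)
  alt_agg <- matrix(1 / 3, L, 3L)
  nz <- rowSums(agg) > 0L
  if (any(nz)) alt_agg[nz, ] <- agg[nz, , drop = FALSE] / rowSums(agg)[nz]
  error_profile(p = p, alt_cond = alt_cond, n_cond = obs,
                alt_agg = alt_agg, n = n, min_obs = min_obs)
}

#' Inject substitution errors into synthetic reads
#'
#' Base i is substituted with probability `p_i` (Bernoulli per base); the
#' substituting nucleotide is drawn from the profile's alternative-base
#' distribution — conditional on the reference base when that cell has
#' enough observations, else the positional aggregate.  `N` bases are never
#' substituted.  The quality string assigns `ref_quality` (37, 'F') to
#' untouched bases and `err_quality` (24, '9') to substituted bases.
#' Profiles shorter than a read are extended with their last position.
#'
#' @param reads data.frame with a `seq` column.
#' @param profile an `error_profile`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param ref_quality,err_quality Phred scores (defaults 37 and 24).
#' @param conditional use the reference-base-conditional alternative
#'   distribution (default) or the positional aggregate only.
#' @return `reads` with `seq` mutated, plus columns `orig_seq`, `qual` and
#'   `n_sub` (substitutions per read).
#' @export
apply_errors <- function(reads, profile, seed = NULL,
                         ref_quality = 37L, err_quality = 24L,
                         conditional = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  qr <- rawToChar(as.raw(ref_quality + 33L))
  qe <- rawToChar(as.raw(err_quality + 33L))
  reads$orig_seq <- reads$seq
  reads$qual <- ""
  reads$n_sub <- 0L
  if (nrow(reads) == 0L) return(reads)
  lens <- nchar(reads$seq)
  for (len in unique(lens)) {
    ix <- which(lens == len)
    n <- length(ix)
    m <- matrix(unlist(strsplit(reads$seq[ix], "")), nrow = n, byrow = TRUE)
    pv <- profile$p[pmin(seq_len(len), length(profile$p))]
    err <- matrix(stats::runif(n * len), n) <
      matrix(pv, n, len, byrow = TRUE)
    err[!(m %in% .BASES)] <- FALSE
    qm <- matrix(qr, n, len)
    if (any(err)) {
      cells <- which(err, arr.ind = TRUE)
      pos <- pmin(cells[, 2L], length(profile$p))
      refb <- m[cells]
      newb <- character(nrow(cells))
      for (b in .BASES) {
        for (pp in unique(pos[refb == b])) {
          sel <- which(refb == b & pos == pp)
          use_cond <- conditional &&
            profile$n_cond[pp, match(b, .BASES)] >= profile$min_obs
          probs <- if (use_cond) {
            profile$alt_cond[pp, match(b, .BASES), ]
          } else {
            profile$alt_agg[pp, ]
          }
          if (sum(probs) <= 0) probs <- rep(1 / 3, 3L)
          newb[sel] <- sample(.ALTS[[b]], length(sel), replace = TRUE,
                              prob = probs)
        }
      }
      m[cells] <- newb
      qm[cells] <- qe
    }
    reads$seq[ix] <- do.call(paste0, lapply(seq_len(len),
                                            function(j) m[, j]))
    reads$qual[ix] <- do.call(paste0, lapply(seq_len(len),
                                             function(j) qm[, j]))
    reads$n_sub[ix] <- rowSums(err)
  }
  reads
}

#' Serialize an error profile to TSV
#' @param profile an `error_profile`.
#' @param path output path.
#' @export
write_error_profile <- function(profile, path) {
  L <- length(profile$p)
  rows <- do.call(rbind, lapply(seq_len(L), function(i) {
    do.call(rbind, lapply(1:4, function(b) {
      # a1..a3 scaled so their sum equals the total rate p at the position
      a <- profile$alt_cond[i, b, ] * profile$p[i]
      data.frame(position = i, ref = .BASES[b], p = profile$p[i],
                 a1 = a[1L], a2 = a[2L], a3 = a[3L],
                 n = profile$n_cond[i, b], stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
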