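# The internal count engine: per-cluster negative-binomial marginals coupled
# by a Gaussian copula, fitted to a real feature-by-cell matrix and sampled
# to produce synthetic cells at a chosen cell number and sequencing depth.

#' Cluster cells of a count matrix (graph-based Louvain)
#'
#' Cells are log-normalized, embedded by their top variable features, and
#' connected in a shared-nearest-neighbour graph whose Louvain communities
#' become the cluster labels.  Used only when the user supplies no labels.
#'
#' @param counts feature-by-cell matrix.
#' @param resolution Louvain resolution (default 1).
#' @param k neighbours per cell (default 10, reduced for tiny data sets).
#' @param seed integer seed.
#' @return character vector of cluster labels, one per cell (column).
#' @export
cluster_cells <- function(counts, resolution = 1, k = 10L, seed = 1L) {
  n <- ncol(counts)
  if (n == 1L) return("1")
  if (n < 4L) {
    warning("too few cells for graph clustering; single cluster")
    return(rep("1", n))
  }
  k <- min(k, n - 1L)
  set.seed(seed)
  x <- as.matrix(counts)
  libsize <- pmax(colSums(x), 1)
  norm <- log1p(t(t(x) / libsize) * 1e4)
  v <- apply(norm, 1L, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(500L, nrow(norm)))]
  emb <- t(norm[top, , drop = FALSE])
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(row) order(row)[seq_len(k)])  # k x n
  # shared-nearest-neighbour weights (Jaccard over neighbour sets)
  adj <- matrix(0, n, n)
  sets <- lapply(seq_len(n), function(i) c(i, nn[, i]))
  for (i in seq_len(n)) {
    for (j in nn[, i]) {
      s <- length(intersect(sets[[i]], sets[[j]]))
      adj[i, j] <- adj[j, i] <- s / (2L * (k + 1L) - s)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.character(igraph::membership(cl))
}

# NB dispersion MLE with method-of-moments start; theta clamped to
# [1e-8, 1e6] (the upper cap is effectively Poisson)
.fit_nb_theta <- function(y, mu) {
  if (mu <= 0) return(1e6)
  v <- stats::var(y)
  if (!is.finite(v) || v <= mu) return(1e6)
  init <- mu^2 / (v - mu)
  th <- tryCatch(
    suppressWarnings(as.numeric(MASS::theta.ml(y, mu = rep(mu, length(y)),
                                               limit = 50))),
    error = function(e) init)
  if (!is.finite(th) || th <= 0) th <- init
  min(max(th, 1e-8), 1e6)
}

# nearest positive-semi-definite correlation matrix (eigenvalue clipping)
.nearest_psd_corr <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  stats::cov2cor(R2)
}

#' Fit the per-cluster NB Gaussian-copula count model
#'
#' For each cell cluster, every feature gets a negative-binomial marginal
#' (mean `mu`, dispersion `theta`, variance `mu + mu^2/theta`); the
#' dependence among the top `copula_top_j` features by mean is captured by a
#' Gaussian copula whose correlation matrix is estimated from normal scores
#' of the mid-distributional transform of the fitted marginals.  Remaining
#' features are sampled independently.
#'
#' @param counts feature-by-cell matrix with dimnames.
#' @param labels per-cell cluster labels; when `NULL`, [cluster_cells()] is
#'   run on `counts`.
#' @param copula_top_j number of features entering the copula (default 500).
#' @param resolution,seed forwarded to [cluster_cells()] when used.
#' @return object of class `count_model`.
#' @export
fit_count_model <- function(counts, labels = NULL, copula_top_j = 500L,
                            resolution = 1, seed = 1L) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%d", seq_len(nrow(counts)))
  }
  if (is.null(labels)) {
    labels <- cluster_cells(counts, resolution = resolution, seed = seed)
  }
  stopifnot(length(labels) == ncol(counts))
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  fits <- lapply(lev, function(kk) {
    x <- counts[, labels == kk, drop = FALSE]
    mu <- rowMeans(x)
    theta <- vapply(seq_len(nrow(x)),
                    function(g) .fit_nb_theta(x[g, ], mu[g]), numeric(1))
    sel <- integer(0)
    R <- NULL
    if (ncol(x) >= 2L) {
      vr <- apply(x, 1L, stats::var)
      ok <- which(mu > 0 & vr > 0)
      if (length(ok) >= 2L) {
        sel <- ok[order(mu[ok], decreasing = TRUE)]
        sel <- sort(sel[seq_len(min(copula_top_j, length(sel)))])
        # mid-distributional transform -> normal scores -> correlation
        z <- vapply(sel, function(g) {
          u <- stats::pnbinom(x[g, ] - 1, size = theta[g], mu = mu[g]) +
            0.5 * stats::dnbinom(x[g, ], size = theta[g], mu = mu[g])
          stats::qnorm(pmin(pmax(u, 1e-10), 1 - 1e-10))
        }, numeric(ncol(x)))
        R <- .nearest_psd_corr(stats::cor(z))
      }
    }
    list(n = ncol(x), mu = mu, theta = theta, sel = sel, R = R)
  })
  names(fits) <- lev
  structure(list(features = rownames(counts),
                 clusters = lev,
                 pi = vapply(fits, function(f) f$n, 0) / ncol(counts),
                 fits = fits,
                 copula_top_j = copula_top_j,
                 labels = labels),
            class = "count_model")
}

#' @exportS3Method print count_model
#' @export
print.count_model <- function(x, ...) {
  cat("NB Gaussian-copula count model\n")
  cat("  features:", length(x$features), "\n")
  cat("  clusters:", length(x$clusters),
      sprintf("(proportions %s)",
              paste(signif(x$pi, 3), collapse = ", ")), "\n")
  nc <- vapply(x$fits, function(f) length(f$sel), 0L)
  cat("  copula features per cluster:", paste(nc, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method summary count_model
#' @export
summary.count_model <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$clusters, function(kk) {
    f <- object$fits[[kk]]
    data.frame(cluster = kk, n_cells = f$n,
               mean_mu = mean(f$mu),
               median_theta = stats::median(f$theta),
               copula_features = length(f$sel),
               stringsAsFactors = FALSE)
  }))
  class(tab) <- c("summary.count_model", "data.frame")
  tab
}

#' @exportS3Method coef count_model
#' @export
coef.count_model <- function(object, cluster = NULL, ...) {
  kk <- if (is.null(cluster)) object$clusters else as.character(cluster)
  out <- lapply(kk, function(k1) {
    f <- object$fits[[k1]]
    data.frame(feature = object$features, cluster = k1,
               mu = f$mu, theta = f$theta, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# sample one cluster's feature-by-cell block
.sample_cluster <- function(fit, features, n, depth_factor) {
  p <- length(features)
  out <- matrix(0L, p, n)
  if (n == 0L) return(out)
  mu <- fit$mu
  theta <- fit$theta
  if (depth_factor > 1) mu <- mu * depth_factor
  sel <- fit$sel
  if (length(sel) >= 2L && !is.null(fit$R)) {
    L <- chol(.nearest_psd_corr(fit$R) + diag(1e-10, length(sel)))
    Z <- matrix(stats::rnorm(n * length(sel)), n) %*% L
    U <- stats::pnorm(Z)
    for (j in seq_along(sel)) {
      g <- sel[j]
      out[g, ] <- stats::qnbinom(U[, j], size = theta[g], mu = mu[g])
    }
  }
  rest <- setdiff(seq_len(p), sel)
  for (g in rest) {
    if (mu[g] > 0) out[g, ] <- stats::rnbinom(n, size = theta[g], mu = mu[g])
  }
  if (depth_factor < 1) {
    nz <- which(out > 0)
    out[nz] <- stats::rbinom(length(nz), out[nz], depth_factor)
  }
  out
}

#' Sample a synthetic feature-by-cell count matrix from a fitted model
#'
#' Synthetic cells are allocated to clusters by a multinomial draw on the
#' fitted cluster proportions (or a supplied assignment); counts come from
#' the Gaussian copula + NB quantile transform.  The sequencing-depth factor
#' `r` is applied as binomial thinning with probability `r` when `r <= 1`
#' and as mean scaling (`mu * r`, `theta` unchanged) when `r > 1`.
#'
#' @param model a `count_model`.
#' @param n_cells number of synthetic cells.
#' @param depth_factor depth scaling factor `r > 0` (default 1).
#' @param cluster_assignment optional explicit cluster label per synthetic
#'   cell (overrides the multinomial draw; used to keep matched matrices on
#'   the same synthetic cells).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return integer matrix (features x cells) with a `clusters` attribute
#'   giving each synthetic cell's cluster.
#' @export
sample_counts <- function(model, n_cells, depth_factor = 1,
                          cluster_assignment = NULL, seed = NULL) {
  if (n_cells < 0L) stop("n_cells must be >= 0")
  if (depth_factor <= 0) stop("depth_factor must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cluster_assignment)) {
    cluster_assignment <- sample(model$clusters, n_cells, replace = TRUE,
                                 prob = model$pi)
  }
  stopifnot(length(cluster_assignment) == n_cells)
  p <- length(model$features)
  out <- matrix(0L, p, n_cells,
                dimnames = list(model$features,
                                sprintf("syncell_%d", seq_len(n_cells))))
  for (kk in model$clusters) {
    ix <- which(cluster_assignment == kk)
    if (length(ix)) {
      out[, ix] <- .sample_cluster(model$fits[[kk]], model$features,
                                   length(ix), depth_factor)
    }
  }
  attr(out, "clusters") <- as.character(cluster_assignment)
  out
}

#' @rdname sample_counts
#' @param object a `count_model`.
#' @param nsim number of synthetic cells.
#' @param ... passed to [sample_counts()].
#' @export
simulate.count_model <- function(object, nsim = 1, seed = NULL, ...) {
  sample_counts(object, n_cells = nsim, seed = seed, ...)
}

#' Construct synthetic counts for gray areas from non-peak donors
#'
#' Each gray area copies the synthetic count row of its nearest upstream
#' (5') trustworthy non-peak, with entries independently masked (set to 0)
#' with probability `max(1 - Lgray/Lnonpeak, 0)`; a gray area at least as
#' long as its donor copies the row unchanged.  A gray area with no upstream
#' non-peak on its chromosome falls back to the nearest downstream one.
#'
#' @param gray,nonpeaks interval tables (same chromosome namespace).
#' @param synth_nonpeak synthetic non-peak-by-cell matrix (rownames =
#'   non-peak ids).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return matrix gray-by-cell, rownames = gray ids, plus a `donor`
#'   attribute naming each gray area's donor non-peak.
#' @export
build_gray_counts <- function(gray, nonpeaks, synth_nonpeak, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, nrow(gray), ncol(synth_nonpeak),
                dimnames = list(gray$id, colnames(synth_nonpeak)))
  donors <- character(nrow(gray))
  for (i in seq_len(nrow(gray))) {
    np <- nonpeaks[nonpeaks$chrom == gray$chrom[i], , drop = FALSE]
    if (nrow(np) == 0L) {
      stop("no non-peak on chromosome ", gray$chrom[i],
           " to serve as donor for ", gray$id[i])
    }
    up <- np[np$end <= gray$start[i], , drop = FALSE]
    donor <- if (nrow(up) > 0L) {
      up[which.max(up$end), , drop = FALSE]
    } else {
      dn <- np[np$start >= gray$end[i], , drop = FALSE]
      dn[which.min(dn$start), , drop = FALSE]
    }
    donors[i] <- donor$id
    lg <- gray$end[i] - gray$start[i]
    ln <- donor$end - donor$start
    p_mask <- max(1 - lg / ln, 0)
    row <- synth_nonpeak[donor$id, ]
    if (p_mask > 0) {
      row[stats::runif(length(row)) < p_mask] <- 0L
    }
    out[i, ] <- row
  }
  attr(out, "donor") <- donors
  out
}

#' Map user-designed ground-truth features to trustworthy donors
#'
#' For every designed feature, the 50 trustworthy features on the same
#' chromosome most similar in length are shortlisted; among them the donor
#' is the one with the largest (`mode = "peak"`) or smallest
#' (`mode = "nonpeak"`) ratio of total read count to feature length.  Ties
#' break by smaller length difference, then leftmost start.  The designed
#' feature inherits the donor's real count row; the signed distance
#' `d = start(designed) - start(donor)` is returned for read relocation.
#'
#' @param designed,trustworthy interval tables.
#' @param real_counts real trustworthy-feature-by-cell matrix (rownames =
#'   trustworthy ids).
#' @param mode `"peak"` or `"nonpeak"`.
#' @param n_candidates shortlist size (default 50).
#' @return list with `counts` (designed-by-cell matrix) and `mapping`
#'   (data.frame designed_id, donor_id, d).
#' @export
map_designed_counts <- function(designed, trustworthy, real_counts,
                                mode = c("peak", "nonpeak"),
                                n_candidates = 50L) {
  mode <- match.arg(mode)
  real_counts <- as.matrix(real_counts)
  totals <- rowSums(real_counts)[trustworthy$id]
  tw_len <- trustworthy$end - trustworthy$start
  ratio <- totals / tw_len
  counts <- matrix(0L, nrow(designed), ncol(real_counts),
                   dimnames = list(designed$id, colnames(real_counts)))
  map <- data.frame(designed_id = designed$id,
                    donor_id = NA_character_, d = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(designed))) {
    on_chr <- which(trustworthy$chrom == designed$chrom[i])
    if (!length(on_chr)) {
      stop("no trustworthy feature on chromosome ", designed$chrom[i])
    }
    dlen <- abs(tw_len[on_chr] - (designed$end[i] - designed$start[i]))
    short <- on_chr[order(dlen, trustworthy$start[on_chr])]
    short <- short[seq_len(min(n_candidates, length(short)))]
    key <- if (mode == "peak") -ratio[short] else ratio[short]
    pick <- short[order(key, abs(tw_len[short] -
                                   (designed$end[i] - designed$start[i])),
                        trustworthy$start[short])][1L]
    map$donor_id[i] <- trustworthy$id[pick]
    map$d[i] <- designed$start[i] - trustworthy$start[pick]
    counts[i, ] <- real_counts[trustworthy$id[pick], ]
  }
  list(counts = counts, mapping = map)
}
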