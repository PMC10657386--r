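# The NB Gaussian-copula count engine: clustering, fitting, sampling,
# depth scaling, gray-area count construction and designed-truth mapping.

test_that("user labels pass through and degenerate cases fall back", {
  tr <- toy_rna()
  m <- count_umis(tr$fx$reads, tr$features, cells = tr$fx$cells)
  labs <- rep(c("a", "b"), length.out = ncol(m))
  fit <- fit_count_model(m, labels = labs)
  expect_identical(fit$labels, labs)
  expect_setequal(fit$clusters, c("a", "b"))

  expect_equal(cluster_cells(matrix(1:5, 5, 1)), "1")
  expect_warning(l3 <- cluster_cells(matrix(1:15, 5, 3)), "single cluster")
  expect_equal(l3, rep("1", 3))
})

test_that("planted populations with disjoint programs are recovered", {
  tr <- toy_rna()
  fx <- make_toy_scrna_reads(tr$genome, tr$features, n_cells = 30L,
                             mean_umis = 6, cluster_structure = 2L,
                             seed = 301L)
  labs <- cluster_cells(as.matrix(fx$umi_matrix), seed = 1L)
  tab <- table(fx$clusters, labs)
  # perfect recovery up to label permutation: one nonzero cell per row/col
  expect_equal(nrow(tab), ncol(tab))
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("NB and copula parameters are recovered from simulated data", {
  set.seed(42)
  n <- 2000L
  rho <- 0.6
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  z <- matrix(rnorm(2 * n), n) %*% L
  u <- pnorm(z)
  x <- rbind(qnbinom(u[, 1], size = 2, mu = 5),
             qnbinom(u[, 2], size = 2, mu = 5),
             rnbinom(n, size = 2, mu = 5))
  rownames(x) <- c("g1", "g2", "g3")
  colnames(x) <- sprintf("c%d", 1:n)
  fit <- fit_count_model(x, labels = rep("1", n))
  f <- fit$fits[["1"]]
  expect_true(all(abs(f$mu - 5) / 5 < 0.05))
  expect_true(all(abs(f$theta - 2) / 2 < 0.20))
  i1 <- match(1L, f$sel)
  i2 <- match(2L, f$sel)
  expect_lt(abs(f$R[i1, i2] - rho), 0.1)

  # all-zero feature gets mu 0 and stays out of the copula
  x0 <- rbind(x, g0 = 0L)
  fit0 <- fit_count_model(x0, labels = rep("1", n))
  expect_equal(fit0$fits[["1"]]$mu[["g0"]], 0)
  expect_false(4L %in% fit0$fits[["1"]]$sel)
})

test_that("fit -> sample -> fit closes on the same parameters", {
  set.seed(43)
  x <- matrix(rnbinom(3 * 2000, size = 2, mu = 5), 3,
              dimnames = list(c("a", "b", "c"), NULL))
  fit1 <- fit_count_model(x, labels = rep("1", 2000))
  y <- sample_counts(fit1, 2000L, seed = 44L)
  fit2 <- fit_count_model(y, labels = rep("1", 2000))
  expect_true(all(abs(fit2$fits[["1"]]$mu - fit1$fits[["1"]]$mu) /
                    fit1$fits[["1"]]$mu < 0.05))
  expect_true(all(abs(fit2$fits[["1"]]$theta - fit1$fits[["1"]]$theta) /
                    fit1$fits[["1"]]$theta < 0.20))
})

test_that("identity copula sampling matches independent NB sampling", {
  model <- structure(list(
    features = c("g1", "g2"), clusters = "1", pi = c("1" = 1),
    fits = list("1" = list(n = 100L, mu = c(g1 = 5, g2 = 5),
                           theta = c(g1 = 2, g2 = 2), sel = 1:2,
                           R = diag(2))),
    copula_top_j = 500L, labels = NULL), class = "count_model")
  y <- sample_counts(model, 5000L, seed = 45L)
  set.seed(46)
  direct <- rnbinom(5000, size = 2, mu = 5)
  for (g in 1:2) {
    ks <- suppressWarnings(stats::ks.test(y[g, ], direct))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("sampling is reproducible and respects edge cases", {
  set.seed(47)
  x <- matrix(rnbinom(4 * 200, size = 3, mu = 4), 4)
  fit <- fit_count_model(x, labels = rep(c("1", "2"), each = 100))
  a <- sample_counts(fit, 50L, seed = 9L)
  b <- sample_counts(fit, 50L, seed = 9L)
  expect_identical(a, b)
  expect_identical(attr(a, "clusters"), attr(b, "clusters"))

  z <- sample_counts(fit, 0L, seed = 1L)
  expect_equal(dim(z), c(4L, 0L))
  expect_error(sample_counts(fit, -1L), "n_cells")
  expect_error(sample_counts(fit, 10L, depth_factor = 0), "depth_factor")

  # simulate() S3 method is the same sampler
  s1 <- simulate(fit, nsim = 20, seed = 5L)
  s2 <- sample_counts(fit, 20L, seed = 5L)
  expect_identical(s1, s2)
})

test_that("depth factors scale expected totals proportionally", {
  set.seed(48)
  x <- matrix(rnbinom(5 * 500, size = 2, mu = 8), 5)
  fit <- fit_count_model(x, labels = rep("1", 500))
  base <- sum(sample_counts(fit, 2000L, depth_factor = 1, seed = 50L))
  half <- sum(sample_counts(fit, 2000L, depth_factor = 0.5, seed = 51L))
  dbl <- sum(sample_counts(fit, 2000L, depth_factor = 2, seed = 52L))
  expect_lt(abs(half / base - 0.5), 0.5 * 0.05)
  expect_lt(abs(dbl / base - 2), 2 * 0.05)
})

test_that("gray areas copy masked rows of their 5' non-peak donor", {
  np <- intervals("chr1", 1000L, 2000L, label = "nonpeak", id = "np1")
  cells <- sprintf("c%d", 1:200)
  synth <- matrix(5L, 1, 200, dimnames = list("np1", cells))

  # gray at least as long as the donor: exact copy
  gray_long <- intervals("chr1", 3000L, 4500L, label = "gray", id = "g1")
  out <- build_gray_counts(gray_long, np, synth, seed = 1L)
  expect_equal(unname(out["g1", ]), rep(5L, 200))
  expect_equal(attr(out, "donor"), "np1")

  # gray half as long: ~half the entries masked
  gray_half <- intervals("chr1", 3000L, 3500L, label = "gray", id = "g2")
  big <- matrix(1L, 1, 100000, dimnames = list("np1", NULL))
  outh <- build_gray_counts(gray_half, np, big, seed = 2L)
  expect_lt(abs(mean(outh == 0) - 0.5), 0.01)

  # no upstream non-peak: nearest downstream donor is used
  gray_first <- intervals("chr1", 0L, 500L, label = "gray", id = "g3")
  outf <- build_gray_counts(gray_first, np, synth, seed = 3L)
  expect_equal(attr(outf, "donor"), "np1")

  expect_error(build_gray_counts(
    intervals("chr2", 0L, 10L, id = "gx"), np, synth), "no non-peak")
})

test_that("designed-truth mapping equals the brute-force donor choice", {
  set.seed(60)
  n <- 60L
  tw <- intervals(rep("chr1", n), seq(0L, by = 2000L, length.out = n),
                  seq(0L, by = 2000L, length.out = n) +
                    sample(200:1200, n, TRUE),
                  label = "peak", id = sprintf("tw%02d", 1:n))
  cells <- sprintf("c%d", 1:5)
  real <- matrix(rpois(n * 5, 20), n, 5, dimnames = list(tw$id, cells))
  des <- intervals(rep("chr1", 3L), c(1e5L, 2e5L, 3e5L) + 0L,
                   c(1e5L, 2e5L, 3e5L) + c(400L, 700L, 950L),
                   label = "gt_peak", id = sprintf("d%d", 1:3))
  res <- map_designed_counts(des, tw, real, mode = "peak")
  lens <- tw$end - tw$start
  ratio <- rowSums(real) / lens
  for (i in 1:3) {
    dl <- abs(lens - (des$end[i] - des$start[i]))
    cand <- order(dl, tw$start)[1:50]
    best <- cand[order(-ratio[cand], dl[cand], tw$start[cand])][1]
    expect_equal(res$mapping$donor_id[i], tw$id[best])
    expect_equal(res$mapping$d[i], des$start[i] - tw$start[best])
    expect_equal(unname(res$counts[i, ]), unname(real[best, ]))
  }

  # single candidate is always chosen
  one <- map_designed_counts(des[1, ], tw[5, ], real[5, , drop = FALSE],
                             mode = "peak")
  expect_equal(one$mapping$donor_id, tw$id[5])

  # non-peak mode: minimal ratio wins, ties to the leftmost start
  tw2 <- intervals(rep("chr1", 3L), c(0L, 5000L, 10000L),
                   c(0L, 5000L, 10000L) + 500L, id = c("a", "b", "c"))
  real2 <- matrix(c(10L, 2L, 2L), 3, 1, dimnames = list(tw2$id, "c1"))
  res2 <- map_designed_counts(des[1, ], tw2, real2, mode = "nonpeak")
  expect_equal(res2$mapping$donor_id, "b")

  expect_error(map_designed_counts(
    intervals("chr9", 0L, 100L, id = "dx"), tw, real), "chromosome")
})
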