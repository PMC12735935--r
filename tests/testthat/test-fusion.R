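test_that("duplicated blocks give identical variates up to sign", {
  set.seed(1)
  X <- scale(matrix(rnorm(30 * 6), 30))
  m <- fit_rgcca(list(X, X), k = 1)
  y1 <- m$variates[[1]][, 1]; y2 <- m$variates[[2]][, 1]
  expect_gt(abs(cor(y1, y2)), 1 - 1e-8)
})

test_that("two-block tau=1 factorial weights match the cross-covariance SVD", {
  set.seed(2)
  for (i in 1:10) {
    X1 <- scale(matrix(rnorm(25 * sample(3:8, 1)), 25))
    X2 <- scale(matrix(rnorm(25 * sample(3:8, 1)), 25))
    m <- fit_rgcca(list(X1, X2), k = 1, scheme = "factorial", tol = 1e-13)
    sv <- svd(crossprod(X1, X2))
    expect_gt(abs(sum(m$weights[[1]][, 1] * sv$u[, 1])), 1 - 1e-8)
    expect_gt(abs(sum(m$weights[[2]][, 1] * sv$v[, 1])), 1 - 1e-8)
  }
})

test_that("the RGCCA criterion is non-decreasing over iterations", {
  set.seed(3)
  for (i in 1:50) {
    nb <- sample(2:4, 1)
    blocks <- lapply(seq_len(nb), function(b)
      scale(matrix(rnorm(20 * sample(3:6, 1)), 20)))
    sch <- sample(c("horst", "factorial", "centroid"), 1)
    m <- suppressWarnings(fit_rgcca(blocks, k = 1, scheme = sch))
    tr <- m$traces[[1]]
    expect_true(all(diff(tr) >= -1e-8 * max(1, abs(tr[1]))),
                label = sprintf("ascent holds (instance %d, %s)", i, sch))
  }
})

test_that("within-block variates from successive deflations are orthogonal", {
  set.seed(4)
  blocks <- lapply(1:3, function(b) scale(matrix(rnorm(40 * 10), 40)))
  m <- fit_rgcca(blocks, k = 3)
  for (b in 1:3) {
    G <- crossprod(m$variates[[b]])
    offdiag <- G[upper.tri(G)] / sqrt(diag(G)[1] * diag(G)[2])
    expect_true(all(abs(offdiag) < 1e-8))
  }
})

test_that("outer AVE matches the brute-force definition and its edge cases", {
  # rank-1 noise-free block is fully explained by one component
  set.seed(5)
  u <- rnorm(20); v <- rnorm(5)
  X1 <- scale(u %*% t(v))
  X2 <- scale(matrix(rnorm(20 * 4), 20))
  m <- fit_rgcca(list(X1, X2), k = 1)
  ave <- compute_ave(m, list(X1, X2))
  expect_equal(ave[1, 1], 100, tolerance = 1e-8)
  # direct-definition oracle on a 5x4 toy block
  set.seed(6)
  T1 <- scale(matrix(rnorm(5 * 4), 5))
  T2 <- scale(matrix(rnorm(5 * 3), 5))
  m2 <- fit_rgcca(list(T1, T2), k = 1)
  y <- m2$variates[[1]][, 1]
  oracle <- 100 * mean(sapply(1:4, function(j) cor(T1[, j], y)^2))
  expect_equal(unname(compute_ave(m2, list(T1, T2))[1, 1]), oracle,
               tolerance = 1e-10)
  expect_true(all(ave[is.finite(ave)] >= 0 & ave[is.finite(ave)] <= 100))
})

test_that("component-count selection follows fixed and marginal rules", {
  expect_equal(select_n_components(NULL, rule = "fixed", k = 3), 3L)
  # marginal profile (50, 12, 8, 3, 2): first marginal < 5 is the 4th -> k = 3
  expect_equal(select_n_components(c(50, 12, 8, 3, 2), rule = "marginal",
                                   threshold = 5), 3L)
  # single dominant component
  expect_equal(select_n_components(c(60, 2, 1), rule = "marginal",
                                   threshold = 5), 1L)
  # nothing below threshold keeps everything
  expect_equal(select_n_components(c(40, 30, 20), rule = "marginal",
                                   threshold = 5), 3L)
})

test_that("variate concatenation preserves order, count and scaling", {
  set.seed(7)
  blocks <- lapply(1:5, function(b)
    block_matrix(scale(matrix(rnorm(43 * 9), 43,
                              dimnames = list(sprintf("s%02d", 1:43), NULL))),
                 c("CBF", "F_p", "F_f", "F_s", "D_s")[b], zscored = TRUE))
  m <- fit_rgcca(blocks, k = 3)
  J <- concatenate_variates(m)
  expect_equal(dim(J), c(43L, 15L))
  prov <- attr(J, "provenance")
  expect_equal(prov$block, rep(c("CBF", "F_p", "F_f", "F_s", "D_s"), each = 3))
  expect_equal(prov$component, rep(1:3, 5))
  expect_true(all(abs(apply(J, 2, sd) - 1) < 1e-9))
  # dropping one block removes exactly k columns
  m4 <- fit_rgcca(blocks[-2], k = 3)
  expect_equal(ncol(concatenate_variates(m4)), 12L)
})

test_that("jICA recovers identity-mixed sign sources exactly", {
  set.seed(8)
  s1 <- rep(c(1, -1), each = 16)
  s2 <- rep(c(1, -1, -1, 1), 8)
  J <- cbind(s1, s2)
  f <- fit_jica(J, n_ic = 2, seed = 1)
  C <- abs(cor(f$loading, J))
  expect_true(all(apply(C, 2, max) > 1 - 1e-8))
})

test_that("jICA is deterministic, reconstructs at full rank, and reduces rank", {
  set.seed(9)
  J <- matrix(rnorm(60 * 8), 60)
  f1 <- fit_jica(J, seed = 4)
  f2 <- fit_jica(J, seed = 4)
  expect_identical(f1, f2)
  Jc <- sweep(J, 2, f1$center)
  rec <- f1$loading %*% f1$source
  expect_lt(norm(Jc - rec, "F") / norm(Jc, "F"), 1e-6)
  # uncorrelated loadings
  cc <- cor(f1$loading)
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-8))
  # rank-deficient input reduces the component count with a warning
  Jr <- cbind(J, J[, 1] + J[, 2])
  expect_warning(fr <- fit_jica(Jr, n_ic = 9), "reduced")
  expect_equal(fr$n_ic, 8L)
})

test_that("five blocks give 15 ICs; a one-column extra block gives 16", {
  sim <- simulate_block_matrices(n_subjects = 43, n_sources = 3, seed = 3)
  fr <- fuse(sim$blocks, k = 3, seed = 1)
  expect_equal(fr$n_ic, 15L)
  expect_equal(dim(fr$scores), c(43L, 16L))  # id column + 15 ICs
  gose <- sim$truth$gose
  keep <- !is.na(gose)
  gb <- zscore_block(block_matrix(
    matrix(gose[keep], ncol = 1,
           dimnames = list(rownames(sim$blocks[[1]]$data)[keep], "gose")),
    "GOSE"))
  blks <- lapply(sim$blocks, function(b)
    zscore_block(block_matrix(b$data[keep, , drop = FALSE], b$modality)))
  fr2 <- fuse(c(blks, list(gb)), k = 3, seed = 1)
  expect_equal(fr2$n_ic, 16L)
})

test_that("planted sources are recovered when extracting the planted count", {
  ok <- 0
  for (r in 1:10) {
    sim <- simulate_block_matrices(n_subjects = 200, n_sources = 3,
                                   effect_size = 1, seed = 400 + r)
    fr <- suppressWarnings(fuse(sim$blocks, k = 3, n_ic = 3, seed = r))
    C <- abs(cor(fr$jica$loading, sim$truth$sources))
    if (min(apply(C, 2, max)) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 7)
})

test_that("block order permutation leaves recovered loadings unchanged up to order/sign", {
  sim <- simulate_block_matrices(n_subjects = 60, n_sources = 2,
                                 noise_sd = 0.1, seed = 11)
  f1 <- suppressWarnings(fuse(sim$blocks, k = 2, seed = 5))
  f2 <- suppressWarnings(fuse(sim$blocks[c(3, 1, 5, 2, 4)], k = 2, seed = 5))
  C <- abs(cor(f1$jica$loading, f2$jica$loading))
  # every component of one run has a (near-)perfect partner in the other
  expect_true(all(apply(C, 1, max) > 0.99))
  expect_true(all(apply(C, 2, max) > 0.99))
})
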