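test_that("BH adjustment matches the brute-force step-up definition", {
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p)
    adj <- numeric(n)
    for (i in seq_len(n)) adj[o[i]] <- min(1, min(p[o][i:n] * n / (i:n)))
    adj
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # dominance and monotonicity
  p <- sort(runif(15))
  a <- bh_fdr(p)
  expect_true(all(a >= p))
  expect_true(all(diff(a) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group comparison reproduces the pooled-t closed form", {
  scores <- cbind(ic = c(1, 2, 3, 4, 5, 6))
  g <- factor(rep(c("A", "B"), each = 3))
  r <- compare_groups(scores, g)
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$mean_A, 2); expect_equal(r$mean_B, 5)
  # CI contains the observed difference
  expect_true(r$ci_lo <= -3 && -3 <= r$ci_hi)
  # identical groups: t = 0, p = 1
  same <- cbind(x = rep(c(1, 2, 3), 2))
  r0 <- compare_groups(same, g)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # FDR dominates raw p
  set.seed(2)
  many <- matrix(rnorm(20 * 8), 20)
  rm_ <- compare_groups(many, factor(rep(c("A", "B"), each = 10)))
  expect_true(all(rm_$p_fdr >= rm_$p))
})

test_that("a planted group effect is detected as the smallest p", {
  hits <- 0
  for (r in 1:20) {
    set.seed(700 + r)
    scores <- matrix(rnorm(200 * 6), 200)
    g <- factor(rep(c("A", "B"), each = 100))
    scores[g == "B", 4] <- scores[g == "B", 4] + 1
    r_ <- compare_groups(scores, g)
    if (which.min(r_$p) == 4) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("Spearman matches the rank-then-Pearson oracle, with ties", {
  expect_equal(unname(correlate_gose(cbind(IC1 = c(1, 2, 3, 4, 5)),
                                     c(1, 2, 3, 4, 5))$rho), 1)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    x <- sample(1:6, n, replace = TRUE)  # heavy integer ties
    y <- rnorm(n) + 0.3 * x
    tab <- correlate_gose(cbind(IC1 = y), x)
    expect_equal(unname(tab$rho), cor(rank(y), rank(x)), tolerance = 1e-12)
  }
  # monotone maps give +/-1
  sc <- cbind(a = c(1, 2, 3, 4))
  expect_equal(unname(correlate_components_rois(
    sc, list(block_matrix(matrix(c(10, 20, 30, 40), 4,
                                 dimnames = list(NULL, "r1")), "CBF")))$rho), 1)
  expect_equal(unname(correlate_components_rois(
    sc, list(block_matrix(matrix(c(40, 30, 20, 10), 4,
                                 dimnames = list(NULL, "r1")), "CBF")))$rho), -1)
})

test_that("component-ROI correlation table applies FDR within IC x modality", {
  set.seed(4)
  n <- 30
  scores <- cbind(IC1 = rnorm(n), IC2 = rnorm(n))
  blk <- block_matrix(matrix(rnorm(n * 10), n,
                             dimnames = list(NULL, sprintf("r%02d", 1:10))),
                      "F_s")
  tab <- correlate_components_rois(scores, list(zscore_block(blk)))
  expect_equal(nrow(tab), 20L)
  for (ic in c("IC1", "IC2")) {
    fam <- tab[tab$component == ic, ]
    expect_equal(fam$p_fdr, bh_fdr(fam$p))
  }
})

test_that("top-region ranking matches a full-sort oracle and breaks ties by label", {
  set.seed(5)
  tab <- data.frame(component = "IC1", modality = "CBF",
                    roi = sprintf("r%02d", 1:20),
                    rho = round(runif(20, -1, 1), 1))
  top <- top_regions(tab, m = 5)
  oracle <- tab[order(-abs(tab$rho), tab$roi), ][1:5, ]
  expect_equal(top$roi, oracle$roi)
  expect_equal(top$rank, 1:5)
  # m larger than the ROI count returns everything ordered
  all_t <- top_regions(tab, m = 50)
  expect_equal(nrow(all_t), 20L)
  expect_true(all(diff(abs(all_t$rho)) <= 0))
})

test_that("voxelwise t-tests agree with t.test and localize a planted shift", {
  dims <- c(5, 5, 2)
  set.seed(6)
  n <- 16
  maps <- lapply(1:n, function(i) array(rnorm(prod(dims)), dims))
  g <- factor(rep(c("HC", "mTBI"), each = 8))
  mask <- array(TRUE, dims)
  vt <- voxelwise_group_ttest(maps, g, mask)
  # per-voxel agreement with stats::t.test
  for (v in c(1, 17, 50)) {
    x <- sapply(maps, function(m) m[[v]])
    tt <- t.test(x[g == "HC"], x[g == "mTBI"], var.equal = TRUE)
    expect_equal(vt$t[[v]], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(vt$p[[v]], tt$p.value, tolerance = 1e-12)
  }
  # identical group maps: all t = 0
  same <- lapply(1:n, function(i) array(rep(1:10, length.out = prod(dims)), dims))
  vt0 <- voxelwise_group_ttest(same, g, mask)
  expect_true(all(vt0$t[mask] == 0))
  # planted shift concentrates significance in the shifted region
  dims2 <- c(8, 8, 4)
  atlas <- make_atlas(dims2, n_regions = 4)
  set.seed(7)
  maps2 <- lapply(1:80, function(i) {
    m <- array(rnorm(prod(dims2), 100, 2), dims2)
    if (i > 40) m[atlas == 2] <- m[atlas == 2] * 1.10
    m
  })
  g2 <- factor(rep(c("HC", "mTBI"), each = 40))
  vt2 <- voxelwise_group_ttest(maps2, g2, atlas == 2)
  expect_gt(mean(vt2$p_fdr[atlas == 2] < 0.05), 0.8)
})

test_that("GOS-E correlation identifies the generating source", {
  hits <- 0
  for (r in 1:10) {
    set.seed(800 + r)
    n <- 100
    scores <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("IC", 1:5)))
    gose <- synthesize_gose(scores[, 3] + rnorm(n, 0, 0.4))
    tab <- correlate_gose(scores, gose)
    if (which.max(abs(tab$rho)) == 3) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # constant GOS-E flagged as undefined
  flat <- correlate_gose(cbind(IC1 = rnorm(10)), rep(6, 10))
  expect_true(flat$flagged[1])
  # per-ROI variant shares the same rank oracle
  set.seed(9)
  blk <- zscore_block(block_matrix(
    matrix(rnorm(40 * 6), 40, dimnames = list(NULL, sprintf("r%d", 1:6))),
    "D_s"))
  gose <- sample(3:8, 40, replace = TRUE)
  tab2 <- correlate_gose_rois(list(blk), gose)
  expect_equal(unname(tab2$rho[1]), cor(rank(blk$data[, 1]), rank(gose)),
               tolerance = 1e-12)
})

test_that("demographics reproduce the printed sex chi-squared and definitional formula", {
  # 24 HC (12 F) vs 19 mTBI (10 F)
  tab <- data.frame(
    group = rep(c("HC", "mTBI"), c(24, 19)),
    sex = c(rep(c("F", "M"), c(12, 12)), rep(c("F", "M"), c(10, 9))),
    age = c(rnorm(24, 29.4, 6.2), rnorm(19, 28, 7.7)))
  rep_ <- demographics(tab)
  expect_equal(round(rep_$sex_chisq$statistic, 3), 0.029)
  expect_equal(round(rep_$sex_chisq$p, 3), 0.864)
  # perfectly balanced table gives exactly zero
  bal <- data.frame(group = rep(c("A", "B"), each = 10),
                    sex = rep(c("F", "M"), 10),
                    age = rnorm(20))
  expect_equal(demographics(bal)$sex_chisq$statistic, 0)
  # definitional oracle sum((O-E)^2/E) on random tables
  set.seed(10)
  for (i in 1:10) {
    counts <- matrix(sample(5:30, 4), 2)
    d <- data.frame(
      group = rep(rep(c("A", "B"), each = 2), times = as.vector(counts)),
      sex = rep(rep(c("F", "M"), 2), times = as.vector(counts)))
    d$age <- rnorm(nrow(d))
    obs <- table(d$sex, factor(d$group))
    E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    oracle <- sum((obs - E)^2 / E)
    expect_equal(demographics(d)$sex_chisq$statistic, oracle,
                 tolerance = 1e-12)
  }
  # Shapiro and Wilcoxon components present and in range
  expect_true(rep_$continuous$age$shapiro$HC$W > 0 &&
                rep_$continuous$age$shapiro$HC$W <= 1)
  expect_true(rep_$continuous$age$wilcoxon$W >= 0)
})
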