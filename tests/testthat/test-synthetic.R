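test_that("phantom ground truth lies on the simplex and within fit bounds", {
  spec <- phantom_spec(grid_shape = c(8, 8, 4))
  cfg <- triexp_config()
  expect_true(all(abs(spec$truth$fp + spec$truth$ff + spec$truth$fs - 1) < 1e-9))
  expect_true(all(spec$truth$fp >= 0 & spec$truth$ff >= 0 & spec$truth$fs >= 0))
  expect_true(all(spec$truth$ds >= cfg$ds_bounds[1] &
                    spec$truth$ds <= cfg$ds_bounds[2]))
  expect_true(all(spec$truth$dp >= cfg$dp_bounds[1] &
                    spec$truth$dp <= cfg$dp_bounds[2]))
  ph <- generate_phantom(spec, make_cohort(2, 2, seed = 1))
  for (s in ph$subjects) {
    tot <- s$fp + s$ff + s$fs
    expect_true(all(abs(tot - 1) < 1e-9))
  }
})

test_that("group effect shifts designated regions and null effect is exact", {
  spec0 <- phantom_spec(grid_shape = c(8, 8, 4),
                        group_effect = list(cbf = 0, fp = 0, fs = 0, ds = 0),
                        subject_jitter = 0)
  coh <- make_cohort(1, 1, seed = 1)
  ph0 <- generate_phantom(spec0, coh)
  expect_equal(ph0$subjects[[1]]$cbf, ph0$subjects[[2]]$cbf)
  # -15% CBF in designated regions only
  spec1 <- phantom_spec(grid_shape = c(8, 8, 4),
                        group_effect = list(cbf = -0.15, fp = 0, fs = 0, ds = 0),
                        effect_regions = 77L, subject_jitter = 0)
  ph1 <- generate_phantom(spec1, coh)
  hc <- ph1$region_truth[[1]]; tb <- ph1$region_truth[[2]]
  expect_equal(tb$cbf[77], 0.85 * hc$cbf[77])
  expect_equal(tb$cbf[-77], hc$cbf[-77])
})

test_that("generators are deterministic given a seed", {
  spec <- phantom_spec(grid_shape = c(8, 8, 4))
  coh <- make_cohort(2, 1, seed = 5)
  expect_identical(generate_phantom(spec, coh), generate_phantom(spec, coh))
  sch <- tiny_scheme()
  p <- tiny_params()
  expect_identical(simulate_dwi(p, sch, snr = 50, seed = 9),
                   simulate_dwi(p, sch, snr = 50, seed = 9))
  expect_identical(simulate_asl(tiny_cbf(), snr = 20, seed = 9),
                   simulate_asl(tiny_cbf(), snr = 20, seed = 9))
  s1 <- simulate_block_matrices(n_subjects = 20, n_rois = 10, seed = 3)
  s2 <- simulate_block_matrices(n_subjects = 20, n_rois = 10, seed = 3)
  expect_identical(s1, s2)
})

test_that("noiseless DWI equals the closed-form forward model", {
  sch <- build_acquisition_scheme()
  p <- tiny_params(fp = 0.1, ff = 0.2, fs = 0.7, dp = 0.01, df = 3e-3,
                   ds = 7e-4, s0 = 1)
  dwi <- simulate_dwi(p, sch, noise_model = "none")
  # independent one-line oracle at b = 1000
  oracle <- 0.1 * exp(-1000 * 0.01) + 0.2 * exp(-1000 * 3e-3) +
    0.7 * exp(-1000 * 7e-4)
  expect_equal(oracle, 0.3575717, tolerance = 1e-6)
  v1000 <- which(sch$bvals == 1000)[1]
  expect_equal(dwi$data[1, 1, 1, v1000], oracle, tolerance = 1e-12)
  # b0 volumes return S0 exactly (fractions sum to 1)
  expect_true(all(dwi$data[, , , sch$bvals == 0] == 1))
  # signal matches the model at every volume
  for (v in seq_along(sch$bvals)) {
    b <- sch$bvals[v]
    expect_equal(dwi$data[2, 2, 1, v],
                 triexp_signal(0.1, 0.2, 0.7, 0.01, 3e-3, 7e-4, b),
                 tolerance = 1e-12)
  }
})

test_that("noise obeys the SNR contract and Rician bias is negligible at high SNR", {
  sch <- build_acquisition_scheme(b_values = 1000, directions_per_b = 3,
                                  n_b0 = 1)
  dims <- c(50, 50, 50)  # 125k voxels
  p <- tiny_params(dims = dims, s0 = 100)
  snr <- 20
  g <- simulate_dwi(p, sch, snr = snr, noise_model = "gaussian", seed = 11)
  clean <- simulate_dwi(p, sch, noise_model = "none")
  noise <- g$data[, , , 1] - clean$data[, , , 1]
  expect_lt(abs(stats::sd(noise) - 100 / snr) / (100 / snr), 0.02)
  # Rician: b0 mean within 0.1% of S0 at snr >= 50
  r <- simulate_dwi(p, sch, snr = 50, noise_model = "rician", seed = 12)
  b0 <- r$data[, , , which(sch$bvals == 0)]
  expect_lt(abs(mean(b0) - 100) / 100, 0.001)
  expect_error(simulate_dwi(p, sch, snr = -1), "snr")
})

test_that("ASL simulation inverts quantification and zero CBF gives zero dM", {
  cbf0 <- tiny_cbf(value = 0)
  s <- simulate_asl(cbf0, n_pairs = 3, snr = Inf)
  expect_equal(split_and_subtract(s), array(0, dim(cbf0)))
  # noiseless round trip to machine precision
  cbf <- tiny_cbf(value = 47.3)
  s2 <- simulate_asl(cbf, n_pairs = 2, snr = Inf)
  q <- quantify_cbf(split_and_subtract(s2), s2$m0, s2$constants)
  expect_true(all(abs(q$cbf - cbf) / cbf < 1e-10))
})

test_that("block-matrix generator plants the stated structure", {
  # rank-1 noise-free single-source construction
  sim <- simulate_block_matrices(n_subjects = 30, n_rois = 8, n_sources = 1,
                                 n_blocks = 2, effect_size = 0, noise_sd = 0,
                                 seed = 2)
  for (b in sim$blocks) {
    sv <- svd(b$data)$d
    expect_lt(sv[2] / sv[1], 1e-9)
  }
  # z-scored columns
  sim2 <- simulate_block_matrices(n_subjects = 40, n_rois = 12, seed = 4)
  for (b in sim2$blocks) {
    expect_true(all(abs(colMeans(b$data)) < 1e-9))
    expect_true(all(abs(apply(b$data, 2, sd) - 1) < 1e-9))
  }
  # planted sources near-orthogonal at large n
  sim3 <- simulate_block_matrices(n_subjects = 2000, n_sources = 3,
                                  effect_size = 0, seed = 5)
  cc <- cor(sim3$truth$sources)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.1))
})

test_that("GOS-E synthesis is monotone with the typical clinical distribution", {
  set.seed(1)
  src <- rnorm(400)
  g <- synthesize_gose(src)
  expect_true(all(g >= 3 & g <= 8))
  expect_true(all(diff(g[order(src)]) >= 0))
  expect_gt(mean(g), 6.0); expect_lt(mean(g), 6.9)
  expect_gt(sd(g), 0.8); expect_lt(sd(g), 1.6)
})

test_that("retest generator matches its closed-form ICC", {
  r0 <- simulate_retest(n_subjects = 10, sigma_subject = 1, sigma_error = 0,
                        seed = 3)
  expect_equal(r0$measurements[, 1], r0$measurements[, 2])
  expect_equal(r0$icc_theoretical, 1)
  r5 <- simulate_retest(sigma_subject = 2, sigma_error = 2)
  expect_equal(r5$icc_theoretical, 0.5)
  # Monte-Carlo recovery at n = 200
  r <- simulate_retest(n_subjects = 200, sigma_subject = sqrt(0.7),
                       sigma_error = sqrt(0.3), seed = 8)
  est <- icc_two_way(r$measurements, variant = "consistency")$icc
  expect_lt(abs(est - r$icc_theoretical), 0.05)
})
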