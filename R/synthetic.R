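#' Phantom specification for the synthetic cohort
#'
#' Defines the voxel grid, the atlas parcellation, region-wise ground-truth
#' values for the tri-exponential IVIM parameters and CBF, the group effect
#' applied to mTBI subjects, and the acquisition noise level. Regional ground
#' truth defaults to physiologically plausible gray/white-matter-like values:
#' perfusion fraction F_p around 5-12%, free-water fraction F_f around
#' 10-25%, slow diffusivity D_s around 0.5-0.9e-3 mm^2/s, fast capillary
#' pseudo-diffusion D_p around 0.03-0.1 mm^2/s, and CBF around
#' 40-70 mL/100g/min, varying smoothly across regions.
#'
#' @param grid_shape integer 3-vector of voxel dimensions.
#' @param n_regions number of atlas regions (default 90).
#' @param snr ratio of noise-free b0 signal to noise standard deviation.
#' @param group_effect named list of per-metric shifts applied to mTBI
#'   subjects in `effect_regions`: multiplicative for `cbf`, `fp`, `fs`
#'   (relative change, e.g. -0.15 for -15%), additive for `ds` (mm^2/s).
#' @param effect_regions integer labels of regions carrying the group effect.
#' @param subject_jitter relative SD of between-subject region-level
#'   variability (lognormal multiplicative jitter).
#' @param s0 unweighted signal amplitude.
#' @param seed integer seed controlling the regional ground-truth draw.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 12),
                         n_regions = 90,
                         snr = 100,
                         group_effect = list(cbf = -0.15, fp = -0.20,
                                             fs = +0.04, ds = 0),
                         effect_regions = c(71, 72, 77, 78),
                         subject_jitter = 0.05,
                         s0 = 100,
                         seed = 42L) {
  if (snr <= 0) stopf("snr must be > 0")
  if (prod(grid_shape) < n_regions)
    stopf("grid too small for %d regions", n_regions)
  set.seed(child_seed(seed, 0L))
  # smooth regional variation around tissue-like central values
  u <- seq(0, 1, length.out = n_regions)
  truth <- data.frame(
    label = seq_len(n_regions),
    fp  = 0.05 + 0.07 * (0.5 + 0.5 * sin(2 * pi * u)) +
      stats::runif(n_regions, -0.005, 0.005),
    ff  = 0.10 + 0.15 * (0.5 + 0.5 * cos(2 * pi * u)) +
      stats::runif(n_regions, -0.01, 0.01),
    dp  = 0.03 + 0.07 * stats::runif(n_regions),
    ds  = 5e-4 + 4e-4 * stats::runif(n_regions),
    cbf = 40 + 30 * stats::runif(n_regions))
  truth$fs <- 1 - truth$fp - truth$ff
  stopifnot(all(truth$fs > 0))
  structure(
    list(grid_shape = as.integer(grid_shape), n_regions = as.integer(n_regions),
         truth = truth, snr = snr, group_effect = group_effect,
         effect_regions = as.integer(effect_regions),
         subject_jitter = subject_jitter, s0 = s0, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Contiguous-parcel atlas labels
#'
#' Splits the voxel grid into `n_regions` contiguous equal-size parcels in
#' linear voxel order; a desk-scale stand-in for a 90-region anatomical
#' parcellation (all voxels labeled, no background).
#'
#' @param grid_shape integer 3-vector.
#' @param n_regions number of parcels.
#' @return an integer 3D array of labels 1..n_regions with a `region_table`
#'   attribute (label, name).
#' @export
make_atlas <- function(grid_shape = c(24, 24, 12), n_regions = 90) {
  nvox <- prod(grid_shape)
  if (nvox < n_regions) stopf("grid too small for %d regions", n_regions)
  lab <- as.integer(ceiling(seq_len(nvox) / (nvox / n_regions)))
  lab[lab > n_regions] <- n_regions
  atlas <- array(lab, dim = grid_shape)
  attr(atlas, "region_table") <- data.frame(
    label = seq_len(n_regions),
    name = sprintf("region_%02d", seq_len(n_regions)))
  atlas
}

#' Cohort design table
#'
#' Builds the subject table for a two-group study: healthy controls (HC) and
#' mild traumatic brain injury (mTBI), with sex, age, a GOS-E functional
#' outcome score for mTBI subjects only, and a visit index (visit 2 marks the
#' retest subset). GOS-E values are synthesized later, from a planted latent
#' source, by [synthesize_gose()]; here the column is initialized to NA.
#'
#' @param n_hc,n_mtbi group sizes (defaults 24 and 19).
#' @param n_retest number of HC subjects with a second visit.
#' @param seed integer seed.
#' @return a data.frame with columns id, group, sex, age, gose, visit.
#' @export
make_cohort <- function(n_hc = 24, n_mtbi = 19, n_retest = 11, seed = 42L) {
  set.seed(child_seed(seed, 1L))
  n <- n_hc + n_mtbi
  d <- data.frame(
    id = sprintf("sub-%03d", seq_len(n)),
    group = factor(rep(c("HC", "mTBI"), c(n_hc, n_mtbi)), c("HC", "mTBI")),
    sex = c(rep(c("F", "M"), length.out = n_hc),
            rep(c("F", "M"), length.out = n_mtbi)),
    age = round(c(stats::rnorm(n_hc, 29.4, 6.2), stats::rnorm(n_mtbi, 28.0, 7.7)), 1),
    gose = NA_integer_,
    visit = 1L)
  attr(d, "retest_ids") <- d$id[seq_len(min(n_retest, n_hc))]
  d
}

#' Map a latent source to GOS-E integers
#'
#' Monotone quantile discretization of a continuous latent recovery source
#' onto the 3-8 range of the Glasgow Outcome Scale-Extended, with bin
#' probabilities chosen to produce the clinically typical mean near 6.4 and
#' SD near 1.1-1.3 for a subacute mTBI cohort.
#'
#' @param source numeric latent values, higher = better outcome.
#' @return integer GOS-E scores in 3..8, monotone in `source`.
#' @export
synthesize_gose <- function(source) {
  probs <- c(0.03, 0.07, 0.12, 0.22, 0.30, 0.26)  # for scores 3..8
  br <- stats::quantile(source, probs = cumsum(probs)[-length(probs)],
                        names = FALSE, type = 7)
  as.integer(3L + findInterval(source, br, left.open = TRUE))
}

#' Generate per-subject ground-truth parameter and CBF maps
#'
#' Produces region-wise constant ground truth volumes per subject. mTBI
#' subjects receive the configured shifts in the designated regions;
#' between-subject variability is seeded multiplicative region-level jitter;
#' fractions are re-normalized to the simplex after any shift so the
#' forward model stays valid.
#'
#' @param spec a [phantom_spec()].
#' @param design a cohort table from [make_cohort()].
#' @return a list with `atlas`, `subjects` (per subject: list of 3D arrays
#'   fp, ff, fs, dp, df, ds, s0 and `cbf`), and `region_truth` (per-subject
#'   region-level truth tables).
#' @export
generate_phantom <- function(spec, design) {
  stopifnot(inherits(spec, "phantom_spec"))
  atlas <- make_atlas(spec$grid_shape, spec$n_regions)
  ge <- spec$group_effect
  cfg <- triexp_config()
  subjects <- vector("list", nrow(design))
  region_truth <- vector("list", nrow(design))
  names(subjects) <- names(region_truth) <- design$id
  for (s in seq_len(nrow(design))) {
    tr <- spec$truth
    if (design$group[s] == "mTBI") {
      r <- tr$label %in% spec$effect_regions
      tr$cbf[r] <- tr$cbf[r] * (1 + (ge$cbf %||% 0))
      tr$fp[r] <- tr$fp[r] * (1 + (ge$fp %||% 0))
      tr$fs[r] <- tr$fs[r] * (1 + (ge$fs %||% 0))
      tr$ds[r] <- tr$ds[r] + (ge$ds %||% 0)
      # re-normalize fractions to the simplex after the shift
      tot <- tr$fp + tr$ff + tr$fs
      tr$fp <- tr$fp / tot; tr$ff <- tr$ff / tot; tr$fs <- tr$fs / tot
    }
    if (spec$subject_jitter > 0) {
      set.seed(child_seed(spec$seed, 100L + s))
      jit <- function(x, rel) x * exp(stats::rnorm(length(x), 0, rel))
      tr$cbf <- jit(tr$cbf, spec$subject_jitter)
      tr$dp <- jit(tr$dp, spec$subject_jitter)
      tr$ds <- jit(tr$ds, spec$subject_jitter)
      tr$fp <- jit(tr$fp, spec$subject_jitter)
      tr$ff <- jit(tr$ff, spec$subject_jitter)
      tot <- tr$fp + tr$ff + tr$fs
      tr$fp <- tr$fp / tot; tr$ff <- tr$ff / tot; tr$fs <- tr$fs / tot
    }
    if (any(tr$ds < cfg$ds_bounds[1] | tr$ds > cfg$ds_bounds[2]) ||
        any(tr$dp < cfg$dp_bounds[1] | tr$dp > cfg$dp_bounds[2]))
      stopf("subject %s: ground-truth diffusivity outside fit bounds; reduce the shift or jitter", design$id[s])
    lab <- as.vector(atlas)
    mk <- function(v) array(v[lab], dim = spec$grid_shape)
    subjects[[s]] <- list(
      fp = mk(tr$fp), ff = mk(tr$ff), fs = mk(tr$fs),
      dp = mk(tr$dp), df = array(cfg$df_fixed, spec$grid_shape),
      ds = mk(tr$ds), s0 = array(spec$s0, spec$grid_shape),
      cbf = mk(tr$cbf))
    region_truth[[s]] <- tr
  }
  list(atlas = atlas, subjects = subjects, region_truth = region_truth)
}

#' Simulate a diffusion-weighted series from ground-truth maps
#'
#' Evaluates the tri-exponential forward model per voxel and volume and adds
#' noise. Rician noise (the default magnitude-MRI model) perturbs the signal
#' as the magnitude of a complex Gaussian deviate with sigma = S0 / snr;
#' Gaussian noise adds the real part only.
#'
#' @param params list of 3D arrays fp, ff, fs, dp, df, ds, s0 (as from
#'   [generate_phantom()]).
#' @param scheme an `acquisition_scheme`.
#' @param snr positive signal-to-noise ratio at b0.
#' @param noise_model one of "rician", "gaussian", "none".
#' @param seed integer seed.
#' @return a `dwi_series`: list with `data` (4D array), `scheme`, `mask`.
#' @export
simulate_dwi <- function(params, scheme, snr = 100,
                         noise_model = c("rician", "gaussian", "none"),
                         seed = 42L) {
  noise_model <- match.arg(noise_model)
  if (snr <= 0) stopf("snr must be > 0")
  validate_scheme(scheme)
  dims <- dim(params$fp)
  nvox <- prod(dims)
  nvol <- length(scheme$bvals)
  fp <- as.vector(params$fp); ff <- as.vector(params$ff)
  fs <- as.vector(params$fs); dp <- as.vector(params$dp)
  df <- as.vector(params$df); ds <- as.vector(params$ds)
  s0 <- as.vector(params$s0)
  sig <- matrix(0, nvox, nvol)
  for (v in seq_len(nvol)) {
    b <- scheme$bvals[v]
    sig[, v] <- s0 * (fp * exp(-b * dp) + ff * exp(-b * df) + fs * exp(-b * ds))
  }
  if (noise_model != "none") {
    set.seed(child_seed(seed, 2L))
    sigma <- s0 / snr
    if (noise_model == "gaussian") {
      sig <- sig + matrix(stats::rnorm(nvox * nvol), nvox, nvol) * sigma
    } else {
      n1 <- matrix(stats::rnorm(nvox * nvol), nvox, nvol) * sigma
      n2 <- matrix(stats::rnorm(nvox * nvol), nvox, nvol) * sigma
      sig <- sqrt((sig + n1)^2 + n2^2)
    }
  }
  structure(
    list(data = array(sig, dim = c(dims, nvol)), scheme = scheme,
         mask = array(TRUE, dim = dims)),
    class = "dwi_series")
}

#' Simulate a pCASL control/label series from a ground-truth CBF map
#'
#' Inverts the single-compartment quantification formula at the ground-truth
#' CBF to obtain the labeling-induced signal difference dM, then emits an
#' interleaved control/label series: control = M0-proportional baseline,
#' label = control - dM, with Gaussian noise per volume at the stated SNR.
#'
#' @param cbf 3D array of ground-truth CBF (mL/100g/min).
#' @param constants an [asl_constants()] list.
#' @param m0 3D array (or scalar) baseline magnetization; default 100.
#' @param n_pairs number of control/label pairs.
#' @param snr SNR of the control image (Inf for noiseless).
#' @param seed integer seed.
#' @return an `asl_series`: list with `data` (4D, control-first interleaved),
#'   `m0`, `constants`, `label_order`.
#' @export
simulate_asl <- function(cbf, constants = asl_constants(), m0 = 100,
                         n_pairs = 20, snr = Inf, seed = 42L) {
  validate_asl_constants(constants)
  dims <- dim(cbf)
  if (length(m0) == 1) m0 <- array(m0, dim = dims)
  dm <- cbf * (2 * constants$alpha * constants$t1b * m0 *
                 (1 - exp(-constants$tau_label / constants$t1b))) *
    exp(-constants$pld / constants$t1b) / (6000 * constants$lambda)
  nvol <- 2L * n_pairs
  dat <- array(0, dim = c(dims, nvol))
  if (is.finite(snr)) set.seed(child_seed(seed, 3L))
  sigma <- if (is.finite(snr)) mean(m0) / snr else 0
  for (p in seq_len(n_pairs)) {
    ctrl <- m0
    labl <- m0 - dm
    if (sigma > 0) {
      ctrl <- ctrl + array(stats::rnorm(prod(dims), 0, sigma), dims)
      labl <- labl + array(stats::rnorm(prod(dims), 0, sigma), dims)
    }
    dat[, , , 2L * p - 1L] <- ctrl
    dat[, , , 2L * p] <- labl
  }
  structure(
    list(data = dat, m0 = m0, constants = constants,
         label_order = "control-first"),
    class = "asl_series")
}

#' Simulate subject-by-ROI block matrices with planted latent structure
#'
#' Direct generator for fusion unit tests, bypassing the imaging stages.
#' Each block is X_b = A S_b + E_b with shared subject-mode sources A
#' (columns i.i.d. from `source_dist`, default unit-variance Laplace),
#' block-specific sparse spatial patterns S_b, and Gaussian noise E_b.
#' Source 1 carries the group effect: its column is shifted between groups
#' by `effect_size` standard deviations. Blocks are z-scored column-wise.
#'
#' @param n_subjects,n_rois,n_sources,n_blocks dimensions.
#' @param source_dist "laplace" or "gaussian".
#' @param effect_size group shift of source 1, in SD units (0 = global null).
#' @param group optional factor of length n_subjects; default balanced
#'   HC/mTBI split.
#' @param noise_sd SD of E_b relative to unit-variance signal (1/noise_sd is
#'   the per-feature SNR).
#' @param pattern_sparsity fraction of ROIs loading on each source.
#' @param seed integer seed.
#' @return list(blocks = list of z-scored `block_matrix`, truth = list(
#'   sources, patterns, effect_source = 1, group, gose)).
#' @export
simulate_block_matrices <- function(n_subjects = 200, n_rois = 90,
                                    n_sources = 3, n_blocks = 5,
                                    source_dist = c("laplace", "gaussian"),
                                    effect_size = 1, group = NULL,
                                    noise_sd = 0.2, pattern_sparsity = 0.3,
                                    seed = 42L) {
  source_dist <- match.arg(source_dist)
  if (n_sources > min(n_subjects, n_rois))
    stopf("n_sources must be <= min(n_subjects, n_rois)")
  set.seed(child_seed(seed, 4L))
  if (is.null(group)) {
    group <- factor(rep(c("HC", "mTBI"), length.out = n_subjects),
                    levels = c("HC", "mTBI"))
  }
  draw <- if (source_dist == "laplace") rlaplace_unit else stats::rnorm
  A <- matrix(draw(n_subjects * n_sources), n_subjects, n_sources)
  if (effect_size != 0)
    A[, 1] <- A[, 1] + ifelse(group == "mTBI", -effect_size / 2, effect_size / 2)
  subj_ids <- sprintf("sub-%03d", seq_len(n_subjects))
  blocks <- vector("list", n_blocks)
  patterns <- vector("list", n_blocks)
  modalities <- c("CBF", "F_p", "F_f", "F_s", "D_s",
                  sprintf("block%d", seq_len(max(0, n_blocks - 5)) + 5))[seq_len(n_blocks)]
  for (b in seq_len(n_blocks)) {
    S <- matrix(0, n_sources, n_rois)
    for (k in seq_len(n_sources)) {
      nz <- sample.int(n_rois, max(1L, round(pattern_sparsity * n_rois)))
      S[k, nz] <- stats::rnorm(length(nz))
    }
    E <- matrix(stats::rnorm(n_subjects * n_rois, 0, noise_sd), n_subjects, n_rois)
    X <- A %*% S + E
    rownames(X) <- subj_ids
    colnames(X) <- sprintf("roi_%02d", seq_len(n_rois))
    blocks[[b]] <- zscore_block(block_matrix(X, modalities[b]))
    patterns[[b]] <- S
  }
  gose <- rep(NA_integer_, n_subjects)
  mtbi <- group == "mTBI"
  if (sum(mtbi) >= 6) gose[mtbi] <- synthesize_gose(A[mtbi, min(2, n_sources)])
  list(blocks = blocks,
       truth = list(sources = A, patterns = patterns, effect_source = 1L,
                    gose_source = min(2L, n_sources), group = group,
                    gose = gose))
}

#' Simulate a two-visit test-retest measurement table
#'
#' Classical one-way random-effects generative model:
#' measurement_{i,v} = mu + u_i + e_{i,v}, u_i ~ N(0, sigma_subject^2),
#' e ~ N(0, sigma_error^2). The theoretical intraclass correlation
#' sigma_subject^2 / (sigma_subject^2 + sigma_error^2) is recorded alongside.
#'
#' @param n_subjects number of subjects.
#' @param mu grand mean.
#' @param sigma_subject,sigma_error standard deviations (>= 0).
#' @param visit_offset fixed systematic offset added to visit 2 (tests the
#'   consistency-vs-agreement distinction).
#' @param seed integer seed.
#' @return a list with `measurements` (n x 2 matrix) and `icc_theoretical`.
#' @export
simulate_retest <- function(n_subjects = 200, mu = 0, sigma_subject = 1,
                            sigma_error = 1, visit_offset = 0, seed = 42L) {
  if (sigma_subject < 0 || sigma_error < 0) stopf("variances must be >= 0")
  set.seed(child_seed(seed, 5L))
  u <- stats::rnorm(n_subjects, 0, sigma_subject)
  e <- matrix(stats::rnorm(n_subjects * 2, 0, sigma_error), n_subjects, 2)
  m <- mu + u + e
  m[, 2] <- m[, 2] + visit_offset
  list(measurements = m,
       icc_theoretical = if (sigma_subject == 0 && sigma_error == 0) NA_real_
       else sigma_subject^2 / (sigma_subject^2 + sigma_error^2))
}
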