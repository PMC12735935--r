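#' Tri-exponential IVIM signal model
#'
#' Relative diffusion-weighted signal
#' S(b)/S0 = F_p exp(-b D_p) + F_f exp(-b D_f) + F_s exp(-b D_s),
#' the three-compartment intravoxel incoherent motion model with a
#' perfusion (pseudo-diffusion) compartment, a free-water-like intermediate
#' compartment, and a slow tissue compartment.
#'
#' @param fp,ff,fs signal fractions (must lie on the unit simplex).
#' @param dp,df,ds diffusivities in mm^2/s.
#' @param b b-value(s), s/mm^2.
#' @return relative signal, same length as `b`.
#' @export
#' @examples
#' triexp_signal(0.1, 0.2, 0.7, 0.01, 3e-3, 7e-4, b = c(0, 1000))
triexp_signal <- function(fp, ff, fs, dp, df, ds, b) {
  if (abs(fp + ff + fs - 1) > 1e-6)
    stopf("fractions must sum to 1 (got %g)", fp + ff + fs)
  if (any(c(dp, df, ds) < 0)) stopf("diffusivities must be >= 0")
  fp * exp(-b * dp) + ff * exp(-b * df) + fs * exp(-b * ds)
}

#' Fit configuration for the two-step tri-exponential procedure
#'
#' Bounds and fixed values follow the physiologically constrained scheme:
#' D_s in [1e-5, 3e-3] mm^2/s (init 1e-3), D_p in [3e-3, 0.2] mm^2/s
#' (init 1e-2), D_f fixed at 3e-3 mm^2/s (free-water diffusivity at body
#' temperature), and the high-b threshold at 1000 s/mm^2 for the step-1
#' mono-exponential D_s estimate.
#'
#' @param ds_bounds,dp_bounds numeric length-2 bounds (mm^2/s).
#' @param ds_init,dp_init initial values.
#' @param df_fixed fixed free-water diffusivity.
#' @param high_b_threshold b-value threshold for step 1 (s/mm^2).
#' @param fractions_init initial (F_p, F_f, F_s).
#' @param ds_fixed_step2 if TRUE, hold D_s at the step-1 estimate during the
#'   full fit instead of leaving it free (initialized) there.
#' @param refit_s0 if TRUE, S0 is a free parameter in step 2; default fixes
#'   it to the b0 shell mean.
#' @param maxiter,ftol optimizer controls for the Levenberg-Marquardt step.
#' @param dropout_noise_floor noise-floor estimate for the signal-dropout
#'   exclusion; voxels whose b0 mean falls below
#'   `dropout_sigma_mult * dropout_noise_floor` are excluded. Default 0
#'   disables the exclusion.
#' @param dropout_sigma_mult multiplier for the dropout threshold.
#' @return a `triexp_config` list.
#' @export
triexp_config <- function(ds_bounds = c(1e-5, 3e-3), ds_init = 1e-3,
                          dp_bounds = c(3e-3, 0.2), dp_init = 1e-2,
                          df_fixed = 3e-3, high_b_threshold = 1000,
                          fractions_init = c(0.1, 0.1, 0.8),
                          ds_fixed_step2 = FALSE, refit_s0 = FALSE,
                          maxiter = 200, ftol = 1e-10,
                          dropout_noise_floor = 0, dropout_sigma_mult = 5) {
  if (ds_bounds[2] > df_fixed + 1e-12 || dp_bounds[1] < df_fixed - 1e-12)
    stopf("compartment ordering requires ds upper bound <= df_fixed <= dp lower bound")
  structure(
    list(ds_bounds = ds_bounds, ds_init = ds_init, dp_bounds = dp_bounds,
         dp_init = dp_init, df_fixed = df_fixed,
         high_b_threshold = high_b_threshold,
         fractions_init = fractions_init, ds_fixed_step2 = ds_fixed_step2,
         refit_s0 = refit_s0, maxiter = maxiter, ftol = ftol,
         dropout_noise_floor = dropout_noise_floor,
         dropout_sigma_mult = dropout_sigma_mult),
    class = "triexp_config")
}

#' Direction-average a DWI series into per-shell means
#'
#' For each b-value (including b0), the arithmetic mean over that shell's
#' volumes per voxel; IVIM decay is treated as isotropic, so shells are
#' averaged before fitting.
#'
#' @param dwi a `dwi_series` (list with `data` 4D, `scheme`, `mask`).
#' @return list with `b` (ascending, b0 first), `signal` (masked-voxel x
#'   shell matrix) and `voxels` (linear indices of masked voxels).
#' @export
shell_average <- function(dwi) {
  scheme <- dwi$scheme
  dims <- dim(dwi$data)
  nvox <- prod(dims[1:3])
  sig <- matrix(dwi$data, nvox, dims[4])
  vox <- which(as.vector(dwi$mask))
  bs <- sort(unique(scheme$bvals))
  out <- matrix(NA_real_, length(vox), length(bs))
  for (i in seq_along(bs)) {
    cols <- which(scheme$bvals == bs[i])
    if (length(cols) == 0) stopf("empty shell at b=%g", bs[i])
    out[, i] <- if (length(cols) == 1) sig[vox, cols]
    else rowMeans(sig[vox, cols, drop = FALSE])
  }
  colnames(out) <- as.character(bs)
  list(b = bs, signal = out, voxels = vox, dims = dims[1:3])
}

#' Step 1: mono-exponential D_s from the high-b shells
#'
#' Log-linear least squares of ln S on b restricted to shells with
#' b >= `high_b_threshold`; the negative slope estimates the slow
#' diffusivity D_s (perfusion and free-water compartments are negligible
#' there). Estimates are clipped into the D_s bounds; clipping and
#' non-positive high-b signals set per-voxel flags. Vectorized over voxels.
#'
#' @param shell_signal voxel x shell matrix of shell means.
#' @param b shell b-values matching the columns.
#' @param config a [triexp_config()].
#' @return list with `ds` (per voxel, NA when excluded), `s0_high`
#'   (intercept), `clipped` and `excluded` logical flags.
#' @export
fit_monoexp_ds <- function(shell_signal, b, config = triexp_config()) {
  hi <- which(b >= config$high_b_threshold)
  if (length(hi) < 2) stopf("need >= 2 shells with b >= %g", config$high_b_threshold)
  S <- shell_signal[, hi, drop = FALSE]
  bad <- rowSums(S <= 0) > 0
  n <- nrow(S)
  ds <- rep(NA_real_, n); s0 <- rep(NA_real_, n)
  if (any(!bad)) {
    logS <- log(S[!bad, , drop = FALSE])
    bb <- b[hi]
    bc <- bb - mean(bb)
    slope <- as.vector(logS %*% bc) / sum(bc^2)
    inter <- rowMeans(logS) - slope * mean(bb)
    ds[!bad] <- -slope
    s0[!bad] <- exp(inter)
  }
  clipped <- !is.na(ds) & (ds < config$ds_bounds[1] | ds > config$ds_bounds[2])
  ds <- pmin(pmax(ds, config$ds_bounds[1]), config$ds_bounds[2])
  list(ds = ds, s0_high = s0, clipped = clipped, excluded = bad)
}

# weighted residual and analytic Jacobian for the bounded
# Levenberg-Marquardt fit; par = (fp, ff, dp, ds) with fs = 1 - fp - ff by
# reparameterization; w are per-shell weights (sqrt of the direction count,
# since a shell mean of n volumes has noise variance sigma^2 / n)
.triexp_resid <- function(par, b, y, df, w) {
  fp <- par[1]; ff <- par[2]; dp <- par[3]; ds <- par[4]
  w * ((fp * exp(-b * dp) + ff * exp(-b * df) + (1 - fp - ff) * exp(-b * ds)) - y)
}

.triexp_jac <- function(par, b, y, df, w) {
  fp <- par[1]; ff <- par[2]; dp <- par[3]; ds <- par[4]
  ep <- exp(-b * dp); ef <- exp(-b * df); es <- exp(-b * ds)
  w * cbind(ep - es, ef - es, -b * fp * ep, -b * (1 - fp - ff) * es)
}

# two-parameter variant on the active simplex boundary F_s = 0
.triexp_resid_fs0 <- function(par, b, y, df, w) {
  fp <- par[1]; dp <- par[2]
  w * ((fp * exp(-b * dp) + (1 - fp) * exp(-b * df)) - y)
}

#' Step 2: full tri-exponential fit of one voxel
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the full
#' three-compartment model over all shells, with D_f fixed, F_s eliminated
#' by the simplex reparameterization F_s = 1 - F_p - F_f, D_s initialized
#' at (or optionally fixed to) the step-1 estimate, and the signal
#' normalized by the b0 mean. If the unconstrained optimum implies
#' F_s < 0, the voxel is re-solved on the simplex boundary (F_s = 0).
#'
#' @param shell_signal numeric vector of shell means for one voxel.
#' @param b shell b-values.
#' @param ds_seed step-1 D_s estimate (NA falls back to `config$ds_init`).
#' @param config a [triexp_config()].
#' @param weights per-shell least-squares weights; the default
#'   `sqrt(n_directions)` reflects that a shell mean over n volumes has
#'   noise SD sigma / sqrt(n). Pass 1 for unweighted.
#' @return named list: fp, ff, fs, dp, df, ds, s0, rmse, converged, boundary.
#' @export
fit_triexp_voxel <- function(shell_signal, b, ds_seed = NA,
                             config = triexp_config(),
                             weights = rep(1, length(b))) {
  s0b <- mean(shell_signal[b == 0])
  if (!is.finite(s0b) || s0b <= 0)
    return(list(fp = NA_real_, ff = NA_real_, fs = NA_real_, dp = NA_real_,
                df = config$df_fixed, ds = NA_real_, s0 = NA_real_,
                rmse = NA_real_, converged = FALSE, boundary = FALSE))
  y <- shell_signal / s0b
  ds0 <- if (is.finite(ds_seed)) min(max(ds_seed, config$ds_bounds[1]),
                                     config$ds_bounds[2]) else config$ds_init
  f0 <- config$fractions_init
  ds_lo <- if (config$ds_fixed_step2) ds0 else config$ds_bounds[1]
  ds_hi <- if (config$ds_fixed_step2) ds0 else config$ds_bounds[2]
  ctrl <- minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                     ftol = config$ftol, ptol = 1e-10)
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = c(f0[1], f0[2], config$dp_init, ds0),
    lower = c(0, 0, config$dp_bounds[1], ds_lo),
    upper = c(1, 1, config$dp_bounds[2], ds_hi),
    fn = .triexp_resid, jac = .triexp_jac,
    b = b, y = y, df = config$df_fixed, w = weights, control = ctrl))
  p <- fit$par
  boundary <- FALSE
  if (1 - p[1] - p[2] < -1e-9) {
    # negative implied F_s: re-solve with F_s pinned to 0 (F_f = 1 - F_p)
    boundary <- TRUE
    fit2 <- suppressWarnings(minpack.lm::nls.lm(
      par = c(min(p[1], 1), max(p[3], config$dp_bounds[1])),
      lower = c(0, config$dp_bounds[1]), upper = c(1, config$dp_bounds[2]),
      fn = .triexp_resid_fs0, b = b, y = y, df = config$df_fixed,
      w = weights, control = ctrl))
    p <- c(fit2$par[1], 1 - fit2$par[1], fit2$par[2], ds0)
    fit <- fit2
    fs <- 0
  } else {
    fs <- max(0, 1 - p[1] - p[2])
  }
  conv <- fit$info %in% 1:4
  list(fp = p[1], ff = p[2], fs = fs, dp = p[3], df = config$df_fixed,
       ds = p[4], s0 = s0b,
       rmse = sqrt(mean((fit$fvec / weights[seq_along(fit$fvec)])^2)),
       converged = conv, boundary = boundary)
}

#' Fit the tri-exponential model over a masked volume
#'
#' Applies [shell_average()], the step-1 [fit_monoexp_ds()] estimate, and
#' the step-2 [fit_triexp_voxel()] fit to every voxel in the mask. Voxels
#' with b0 shell mean below the configured dropout threshold, or with
#' non-positive high-b signal, are excluded and flagged rather than fitted.
#'
#' @param dwi a `dwi_series`.
#' @param config a [triexp_config()].
#' @param verbose print completion statistics.
#' @return a `triexp_param_map`: list of 3D arrays (fp, ff, fs, dp, df, ds,
#'   s0, rmse), logical arrays `converged`, `excluded`, `boundary`, and a
#'   `stats` list (n_fitted, n_excluded, n_nonconverged).
#' @export
fit_triexp_volume <- function(dwi, config = triexp_config(), verbose = FALSE) {
  sa <- shell_average(dwi)
  dims <- sa$dims
  n <- length(sa$voxels)
  step1 <- if (n > 0) fit_monoexp_ds(sa$signal, sa$b, config) else NULL
  mk <- function() array(NA_real_, dims)
  out <- list(fp = mk(), ff = mk(), fs = mk(), dp = mk(),
              df = mk(), ds = mk(), s0 = mk(), rmse = mk())
  converged <- array(FALSE, dims)
  excluded <- array(FALSE, dims)
  boundary <- array(FALSE, dims)
  dropout_thr <- config$dropout_sigma_mult * config$dropout_noise_floor
  shell_w <- sqrt(vapply(sa$b, function(bb) sum(dwi$scheme$bvals == bb), 0))
  n_fitted <- 0L
  if (n > 0) {
    b0_mean <- sa$signal[, which(sa$b == 0)[1]]
    for (i in seq_len(n)) {
      v <- sa$voxels[i]
      if (step1$excluded[i] || b0_mean[i] <= dropout_thr) {
        excluded[v] <- TRUE
        next
      }
      r <- fit_triexp_voxel(sa$signal[i, ], sa$b, step1$ds[i], config,
                            weights = shell_w)
      out$fp[v] <- r$fp; out$ff[v] <- r$ff; out$fs[v] <- r$fs
      out$dp[v] <- r$dp; out$df[v] <- r$df; out$ds[v] <- r$ds
      out$s0[v] <- r$s0; out$rmse[v] <- r$rmse
      converged[v] <- r$converged
      boundary[v] <- r$boundary
      if (!r$converged) excluded[v] <- FALSE  # flagged, kept visible
      n_fitted <- n_fitted + 1L
    }
  }
  stats <- list(n_masked = n, n_fitted = n_fitted,
                n_excluded = sum(excluded),
                n_nonconverged = sum(!converged[sa$voxels]) - sum(excluded))
  if (verbose)
    message(sprintf("triexp fit: %d/%d voxels fitted, %d excluded, %d non-converged",
                    stats$n_fitted, stats$n_masked, stats$n_excluded,
                    stats$n_nonconverged))
  structure(c(out, list(converged = converged, excluded = excluded,
                        boundary = boundary, stats = stats)),
            class = "triexp_param_map")
}
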