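#' pCASL quantification constants
#'
#' Labeling and tissue constants for the single-compartment kinetic model:
#' labeling duration 1.8 s and post-labeling delay 2.0 s (acquisition
#' protocol values); blood-tissue partition coefficient lambda = 0.9 mL/g,
#' labeling efficiency alpha = 0.85 and blood T1 = 1.650 s follow the ASL
#' consensus single-compartment model and are overridable.
#'
#' @param tau_label labeling duration (s).
#' @param pld post-labeling delay (s).
#' @param lambda blood-tissue partition coefficient (mL/g).
#' @param alpha labeling efficiency, in (0, 1].
#' @param t1b longitudinal relaxation time of arterial blood (s).
#' @return an `asl_constants` list.
#' @export
asl_constants <- function(tau_label = 1.8, pld = 2.0, lambda = 0.9,
                          alpha = 0.85, t1b = 1.650) {
  structure(list(tau_label = tau_label, pld = pld, lambda = lambda,
                 alpha = alpha, t1b = t1b),
            class = "asl_constants")
}

validate_asl_constants <- function(x) {
  stopifnot(inherits(x, "asl_constants"))
  vals <- unlist(x)
  if (any(vals <= 0)) stopf("all ASL constants must be strictly positive")
  if (x$alpha > 1) stopf("labeling efficiency alpha must be in (0, 1]")
  invisible(TRUE)
}

#' Split an interleaved series and form the perfusion-weighted difference
#'
#' Splits the 4D series into control and label volumes according to the
#' label-order flag and returns dM = mean(control) - mean(label), the grand
#' means taken over all repetitions.
#'
#' @param series an `asl_series` (list with `data` 4D, `label_order`).
#' @return 3D array dM.
#' @export
split_and_subtract <- function(series) {
  dat <- series$data
  nvol <- dim(dat)[4]
  if (nvol %% 2 != 0) stopf("ASL series must have an even volume count (got %d)", nvol)
  order <- series$label_order %||% "control-first"
  idx <- seq_len(nvol)
  ctrl_idx <- if (order == "control-first") idx[idx %% 2 == 1] else idx[idx %% 2 == 0]
  labl_idx <- setdiff(idx, ctrl_idx)
  ctrl <- apply(dat[, , , ctrl_idx, drop = FALSE], 1:3, mean)
  labl <- apply(dat[, , , labl_idx, drop = FALSE], 1:3, mean)
  ctrl - labl
}

#' Voxelwise mean over all volumes
#'
#' The baseline image: the arithmetic mean of every volume in the series
#' (control and label alike).
#'
#' @param series an `asl_series` or a bare 4D array.
#' @return 3D array.
#' @export
mean_baseline <- function(series) {
  dat <- if (is.list(series)) series$data else series
  if (length(dim(dat)) == 3) return(dat)
  if (dim(dat)[4] < 1) stopf("need >= 1 volume")
  apply(dat, 1:3, mean)
}

#' Quantify cerebral blood flow from the labeling difference
#'
#' Single-compartment kinetic model:
#' CBF = 6000 * lambda * dM * exp(PLD / T1b) /
#'       (2 * alpha * T1b * M0 * (1 - exp(-tau_label / T1b)))
#' in mL/100g/min. Voxels with non-positive M0 are masked out (NA) and
#' counted.
#'
#' @param dm 3D array of control-label difference.
#' @param m0 3D array (or scalar) of baseline magnetization.
#' @param constants an [asl_constants()] list.
#' @return a `cbf_map`: list with `cbf` (3D array, NA where M0 <= 0),
#'   `mask`, `n_masked_out`, and the constants used.
#' @export
quantify_cbf <- function(dm, m0, constants = asl_constants()) {
  validate_asl_constants(constants)
  if (length(m0) == 1) m0 <- array(m0, dim = dim(dm))
  ok <- m0 > 0
  cbf <- array(NA_real_, dim = dim(dm))
  cbf[ok] <- 6000 * constants$lambda * dm[ok] *
    exp(constants$pld / constants$t1b) /
    (2 * constants$alpha * constants$t1b * m0[ok] *
       (1 - exp(-constants$tau_label / constants$t1b)))
  structure(list(cbf = cbf, mask = ok, n_masked_out = sum(!ok),
                 constants = constants),
            class = "cbf_map")
}
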