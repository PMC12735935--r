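#' Two-way intraclass correlation from a subjects-by-visits table
#'
#' Computes ICC from the two-way ANOVA mean squares (rows = subjects,
#' columns = visits/raters, k visits):
#' consistency ICC(3,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E);
#' absolute-agreement ICC(2,1) =
#' (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)).
#' Estimates below `floor` are clipped and flagged; a zero-variance table
#' yields NA with a flag.
#'
#' @param measurements n x k numeric matrix (k = 2 for test-retest).
#' @param variant "consistency" (ICC(3,1), default) or "agreement"
#'   (ICC(2,1)).
#' @param floor lower clip (default -1).
#' @return list: icc, variant, ms (MS_R, MS_C, MS_E), clipped, degenerate.
#' @export
icc_two_way <- function(measurements,
                        variant = c("consistency", "agreement"),
                        floor = -1) {
  variant <- match.arg(variant)
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stopf("need >= 3 subjects")
  if (anyNA(m)) stopf("missing cells are not supported")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ss_r <- k * sum((rm_ - grand)^2)
  ss_c <- n * sum((cm - grand)^2)
  ss_t <- sum((m - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (ss_t < .Machine$double.eps)
    return(list(icc = NA_real_, variant = variant,
                ms = c(ms_r = ms_r, ms_c = ms_c, ms_e = ms_e),
                clipped = FALSE, degenerate = TRUE))
  denom <- if (variant == "consistency") ms_r + (k - 1) * ms_e
  else ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  icc <- (ms_r - ms_e) / denom
  clipped <- is.finite(icc) && icc < floor
  if (clipped) icc <- floor
  list(icc = icc, variant = variant,
       ms = c(ms_r = ms_r, ms_c = ms_c, ms_e = ms_e),
       clipped = clipped, degenerate = FALSE)
}

#' Voxelwise test-retest ICC map
#'
#' Applies the two-way ICC at every masked voxel across subjects' two-visit
#' maps, vectorized over voxels, and summarizes reliability as the in-mask
#' mean and SD (excluding degenerate voxels).
#'
#' @param visit1,visit2 named lists of per-subject 3D arrays (same subject
#'   order) or 4D arrays with subjects last.
#' @param mask logical 3D array.
#' @param variant "consistency" or "agreement".
#' @return an `icc_result`: `icc` 3D array (NA outside mask / degenerate),
#'   `summary` (mean, sd, n_voxels, n_degenerate), `variant`.
#' @export
icc_map <- function(visit1, visit2, mask = NULL,
                    variant = c("consistency", "agreement")) {
  variant <- match.arg(variant)
  as_mat <- function(v) {
    if (is.list(v)) {
      dims <- dim(v[[1]])
      list(m = vapply(v, as.vector, numeric(prod(dims))), dims = dims)
    } else {
      dims <- dim(v)[1:3]
      list(m = matrix(v, prod(dims), dim(v)[4]), dims = dims)
    }
  }
  a1 <- as_mat(visit1); a2 <- as_mat(visit2)
  if (!identical(a1$dims, a2$dims) || ncol(a1$m) != ncol(a2$m))
    stopf("visit volumes must match in grid and subject count")
  n <- ncol(a1$m)
  if (n < 3) stopf("need >= 3 subjects")
  if (is.null(mask)) mask <- array(TRUE, a1$dims)
  vox <- which(as.vector(mask))
  x1 <- a1$m[vox, , drop = FALSE]; x2 <- a2$m[vox, , drop = FALSE]
  k <- 2
  grand <- (rowMeans(x1) + rowMeans(x2)) / 2
  rmean <- (x1 + x2) / 2
  cm1 <- rowMeans(x1); cm2 <- rowMeans(x2)
  ss_r <- k * rowSums((rmean - grand)^2)
  ss_c <- n * ((cm1 - grand)^2 + (cm2 - grand)^2)
  ss_t <- rowSums((x1 - grand)^2) + rowSums((x2 - grand)^2)
  ss_e <- pmax(0, ss_t - ss_r - ss_c)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  degenerate <- ss_t < .Machine$double.eps
  denom <- if (variant == "consistency") ms_r + (k - 1) * ms_e
  else ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  icc <- ifelse(degenerate | denom <= 0, NA_real_, (ms_r - ms_e) / denom)
  # identical visits: zero error variance gives ICC = 1 exactly
  icc[!degenerate & ms_e < .Machine$double.eps & ms_r > 0 &
        (variant == "consistency" | ms_c < .Machine$double.eps)] <- 1
  out <- array(NA_real_, a1$dims)
  out[vox] <- icc
  ok <- is.finite(icc)
  structure(list(icc = out,
                 summary = list(mean = mean(icc[ok]), sd = stats::sd(icc[ok]),
                                n_voxels = sum(ok),
                                n_degenerate = sum(!ok)),
                 variant = variant),
            class = "icc_result")
}
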