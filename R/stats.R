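#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' preserves the input order. Thin wrapper around [stats::p.adjust()]
#' exposed under the pipeline's name for traceable output metadata.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs propagate).
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-component two-sample group comparison
#'
#' Two-sample t-test (pooled-variance by default, Welch selectable) of each
#' IC's subject scores between the two groups, with BH-FDR across
#' components, group means, and the 95% confidence interval of the mean
#' difference (group 1 minus group 2).
#'
#' @param scores subjects x components matrix or data.frame of numeric
#'   scores.
#' @param group two-level factor aligned with the rows.
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return a data.frame: component, t, p, p_fdr, mean_<level1>,
#'   mean_<level2>, ci_lo, ci_hi, degenerate.
#' @export
compare_groups <- function(scores, group, var_equal = TRUE) {
  scores <- as.matrix(scores)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stopf("group must have exactly 2 levels")
  if (any(table(group) < 2)) stopf("each group needs n >= 2")
  lv <- levels(group)
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    x <- scores[group == lv[1], j]
    y <- scores[group == lv[2], j]
    degenerate <- stats::sd(x) < .Machine$double.eps &&
      stats::sd(y) < .Machine$double.eps
    if (degenerate && mean(x) == mean(y)) {
      return(data.frame(component = colnames(scores)[j] %||% j,
                        t = 0, p = 1, m1 = mean(x), m2 = mean(y),
                        ci_lo = 0, ci_hi = 0, degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(component = colnames(scores)[j] %||% j,
               t = unname(tt$statistic), p = tt$p.value,
               m1 = mean(x), m2 = mean(y),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  names(out)[names(out) == "m1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "m2"] <- paste0("mean_", lv[2])
  out[, c("component", "t", "p", "p_fdr", paste0("mean_", lv),
          "ci_lo", "ci_hi", "degenerate")]
}

# tie-corrected Spearman correlation with t-approximation p-value
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) < .Machine$double.eps ||
      stats::sd(y) < .Machine$double.eps)
    return(c(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Spearman correlations between IC scores and ROI features
#'
#' Tie-corrected Spearman rho per (IC, modality, ROI), with the p-value
#' from the t-approximation and BH-FDR applied within each IC x modality
#' family (90 tests per family for a 90-region atlas). Constant columns
#' yield NA and are flagged.
#'
#' @param scores subjects x ICs matrix/data.frame.
#' @param zblocks list of z-scored `block_matrix` objects aligned with the
#'   score rows.
#' @return a data.frame: component, modality, roi, rho, p, p_fdr, flagged.
#' @export
correlate_components_rois <- function(scores, zblocks) {
  scores <- as.matrix(scores)
  out <- list()
  for (blk in zblocks) {
    m <- if (inherits(blk, "block_matrix")) blk$data else blk
    modality <- if (inherits(blk, "block_matrix")) blk$modality else "unknown"
    if (nrow(m) != nrow(scores)) stopf("subject sets differ between scores and block '%s'", modality)
    for (j in seq_len(ncol(scores))) {
      res <- t(apply(m, 2, function(col) spearman_test(scores[, j], col)))
      d <- data.frame(component = colnames(scores)[j] %||% sprintf("IC%d", j),
                      modality = modality,
                      roi = colnames(m) %||% seq_len(ncol(m)),
                      rho = res[, "rho"], p = res[, "p"])
      d$p_fdr <- bh_fdr(d$p)
      d$flagged <- !is.finite(d$rho)
      out[[length(out) + 1]] <- d
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Top contributing regions per component and modality
#'
#' The `m` ROIs with the largest absolute correlation per IC x modality,
#' ordered by decreasing |rho|; ties are broken by ascending ROI label.
#'
#' @param corr_table output of [correlate_components_rois()] (or any table
#'   with component, modality, roi, rho columns).
#' @param m number of regions to keep (default 5).
#' @return subset of `corr_table` with a `rank` column.
#' @export
top_regions <- function(corr_table, m = 5) {
  if (nrow(corr_table) == 0) stopf("empty correlation table")
  split_keys <- interaction(corr_table$component, corr_table$modality, drop = TRUE)
  parts <- lapply(split(corr_table, split_keys), function(d) {
    d <- d[order(-abs(d$rho), d$roi), ]
    d <- utils::head(d, m)
    d$rank <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Voxelwise two-sample t-test within an ROI
#'
#' Vectorized pooled-variance (or Welch) two-sample t-test per voxel inside
#' the ROI mask, with BH-FDR across the ROI's voxels. All-equal voxels are
#' flagged (t = 0, p = 1).
#'
#' @param maps named list of per-subject 3D arrays, or a 4D array with the
#'   subject dimension last.
#' @param group two-level factor aligned with subjects.
#' @param roi_mask logical 3D array (the test family).
#' @param var_equal pooled (TRUE) or Welch.
#' @return list with 3D arrays `t`, `p`, `p_fdr` (NA outside the mask),
#'   `flagged`, and `n_voxels`.
#' @export
voxelwise_group_ttest <- function(maps, group, roi_mask, var_equal = TRUE) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    M <- vapply(maps, function(a) as.vector(a), numeric(prod(dims)))
  } else {
    dims <- dim(maps)[1:3]
    M <- matrix(maps, prod(dims), dim(maps)[4])
  }
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stopf("group must have exactly 2 levels")
  vox <- which(as.vector(roi_mask))
  if (length(vox) == 0) stopf("empty ROI mask")
  g1 <- group == levels(group)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  x1 <- M[vox, g1, drop = FALSE]; x2 <- M[vox, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  flat <- se < .Machine$double.eps
  tval <- ifelse(flat, 0, (m1 - m2) / se)
  pval <- ifelse(flat, 1, 2 * stats::pt(-abs(tval), df))
  pfdr <- bh_fdr(pval)
  put <- function(v) { a <- array(NA_real_, dims); a[vox] <- v; a }
  list(t = put(tval), p = put(pval), p_fdr = put(pfdr),
       flagged = put(as.numeric(flat)), n_voxels = length(vox))
}

#' Spearman correlation of IC scores with GOS-E outcome
#'
#' Per-IC tie-corrected Spearman correlation between subject scores and
#' GOS-E functional outcome within the patient group, with BH-FDR across
#' components.
#'
#' @param scores subjects x ICs matrix/data.frame (patient subjects only).
#' @param gose integer GOS-E scores aligned with the rows.
#' @return data.frame: component, rho, p, p_fdr, flagged.
#' @export
correlate_gose <- function(scores, gose) {
  scores <- as.matrix(scores)
  if (length(gose) != nrow(scores)) stopf("gose length must match score rows")
  if (sum(is.finite(gose)) < 5) stopf("need >= 5 subjects with GOS-E")
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    r <- spearman_test(scores[, j], gose)
    data.frame(component = colnames(scores)[j] %||% sprintf("IC%d", j),
               rho = r["rho"], p = r["p"], flagged = !is.finite(r["rho"]))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("component", "rho", "p", "p_fdr", "flagged")]
}

#' Spearman correlation of ROI features with GOS-E outcome
#'
#' Per ROI x modality tie-corrected Spearman correlation with GOS-E, FDR
#' within each modality's family of regions.
#'
#' @param zblocks list of z-scored `block_matrix` objects (patient rows).
#' @param gose GOS-E scores aligned with rows.
#' @return data.frame: modality, roi, rho, p, p_fdr, flagged.
#' @export
correlate_gose_rois <- function(zblocks, gose) {
  out <- list()
  for (blk in zblocks) {
    m <- if (inherits(blk, "block_matrix")) blk$data else blk
    modality <- if (inherits(blk, "block_matrix")) blk$modality else "unknown"
    res <- t(apply(m, 2, function(col) spearman_test(col, gose)))
    d <- data.frame(modality = modality,
                    roi = colnames(m) %||% seq_len(ncol(m)),
                    rho = res[, "rho"], p = res[, "p"])
    d$p_fdr <- bh_fdr(d$p)
    d$flagged <- !is.finite(d$rho)
    out[[length(out) + 1]] <- d
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Demographic and motion comparisons between groups
#'
#' Pearson chi-squared on the 2x2 sex-by-group table without continuity
#' correction (df = 1); Shapiro-Wilk normality per group and Wilcoxon
#' rank-sum group comparison (normal approximation with continuity and tie
#' correction) for each continuous variable.
#'
#' @param subject_table data.frame with `group`, `sex`, and the continuous
#'   columns named in `continuous`.
#' @param continuous character vector of continuous column names (default
#'   "age" plus any column starting with "motion").
#' @return a `demographics_report`: list with `sex_chisq` (statistic, p,
#'   table, expected_warning) and `continuous` (per variable: per-group
#'   Shapiro W/p and Wilcoxon W/p).
#' @export
demographics <- function(subject_table, continuous = NULL) {
  group <- droplevels(as.factor(subject_table$group))
  if (nlevels(group) != 2) stopf("need exactly 2 groups")
  if (is.null(continuous))
    continuous <- intersect(c("age", grep("^motion", names(subject_table), value = TRUE)),
                            names(subject_table))
  tab <- table(subject_table$sex, group)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expected_warning <- any(cs$expected < 5)
  if (expected_warning) warnf("chi-squared: some expected counts < 5")
  cont <- lapply(continuous, function(v) {
    x <- subject_table[[v]]
    sw <- lapply(levels(group), function(g) {
      xi <- x[group == g]
      if (length(unique(xi)) < 3) return(list(W = NA_real_, p = NA_real_))
      s <- stats::shapiro.test(xi)
      list(W = unname(s$statistic), p = s$p.value)
    })
    names(sw) <- levels(group)
    wt <- suppressWarnings(stats::wilcox.test(x ~ group, exact = FALSE,
                                              correct = TRUE))
    list(shapiro = sw, wilcoxon = list(W = unname(wt$statistic), p = wt$p.value))
  })
  names(cont) <- continuous
  structure(list(sex_chisq = list(statistic = unname(cs$statistic),
                                  p = cs$p.value, table = tab,
                                  expected_warning = expected_warning),
                 continuous = cont),
            class = "demographics_report")
}
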