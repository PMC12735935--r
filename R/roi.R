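#' Construct a subject-by-ROI block matrix
#'
#' Container for one modality's subject x feature matrix, with explicit
#' subject and feature identifiers and a z-scoring flag.
#'
#' @param data numeric matrix, subjects in rows (rownames = subject ids),
#'   ROIs in columns.
#' @param modality modality name (e.g. "CBF", "F_p", "GOSE").
#' @param zscored logical.
#' @param zero_variance logical vector flagging degenerate columns.
#' @return a `block_matrix`.
#' @export
block_matrix <- function(data, modality, zscored = FALSE,
                         zero_variance = rep(FALSE, ncol(data))) {
  stopifnot(is.matrix(data))
  if (anyNA(data)) stopf("block '%s' has missing cells", modality)
  structure(list(data = data, modality = modality, zscored = zscored,
                 zero_variance = zero_variance),
            class = "block_matrix")
}

#' @export
print.block_matrix <- function(x, ...) {
  cat(sprintf("block_matrix '%s': %d subjects x %d features%s\n",
              x$modality, nrow(x$data), ncol(x$data),
              if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' Mean map value per atlas region
#'
#' Arithmetic mean of in-region, in-mask, finite voxels for each atlas
#' label, returned in ascending label order. Regions with no valid voxel
#' yield NA with a warning.
#'
#' @param map 3D array.
#' @param atlas integer 3D label array (0 = background), same grid.
#' @param mask optional logical 3D array.
#' @param labels labels to extract; default all non-zero labels present in
#'   the atlas's region table (or the atlas itself).
#' @return named numeric vector of region means (names = labels).
#' @export
extract_roi_means <- function(map, atlas, mask = NULL, labels = NULL) {
  if (!identical(dim(map), dim(atlas)))
    stopf("map and atlas grids differ")
  rt <- attr(atlas, "region_table")
  if (is.null(labels))
    labels <- if (!is.null(rt)) sort(rt$label) else sort(setdiff(unique(as.vector(atlas)), 0))
  valid <- is.finite(map)
  if (!is.null(mask)) valid <- valid & as.logical(mask)
  lab <- as.vector(atlas)
  keep <- valid & lab > 0
  sums <- tapply(as.vector(map)[keep], lab[keep], mean)
  out <- stats::setNames(rep(NA_real_, length(labels)), labels)
  hit <- intersect(names(sums), names(out))
  out[hit] <- sums[hit]
  if (anyNA(out))
    warnf("%d region(s) with zero valid voxels: %s", sum(is.na(out)),
          paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Assemble one modality's block matrix from per-subject maps
#'
#' Rows follow the order of `subject_ids`; columns follow ascending atlas
#' label. Each subject must have a map.
#'
#' @param maps named list of 3D arrays (names = subject ids).
#' @param atlas integer label array.
#' @param modality modality name.
#' @param subject_ids subject ordering; default `names(maps)`.
#' @param mask optional logical array applied to every subject.
#' @return an (un-z-scored) `block_matrix`.
#' @export
assemble_block <- function(maps, atlas, modality,
                           subject_ids = names(maps), mask = NULL) {
  missing <- setdiff(subject_ids, names(maps))
  if (length(missing) > 0)
    stopf("missing map(s) for subject(s): %s", paste(missing, collapse = ", "))
  rows <- lapply(subject_ids, function(id)
    extract_roi_means(maps[[id]], atlas, mask = mask))
  m <- do.call(rbind, rows)
  rownames(m) <- subject_ids
  block_matrix(m, modality)
}

#' Z-score a block matrix across subjects
#'
#' Per column: subtract the mean and divide by the sample SD (n-1
#' denominator). Zero-variance columns are set to 0 and flagged rather
#' than dropped, preserving the column contract.
#'
#' @param block a `block_matrix` or bare matrix.
#' @return a z-scored `block_matrix`.
#' @export
zscore_block <- function(block) {
  m <- if (inherits(block, "block_matrix")) block$data else block
  if (nrow(m) < 2) stopf("z-scoring needs >= 2 subjects")
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  zero <- !is.finite(sd) | sd < .Machine$double.eps
  z <- sweep(m, 2, mu, "-")
  z[, !zero] <- sweep(z[, !zero, drop = FALSE], 2, sd[!zero], "/")
  z[, zero] <- 0
  block_matrix(z,
               modality = if (inherits(block, "block_matrix")) block$modality else "unknown",
               zscored = TRUE, zero_variance = zero)
}
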