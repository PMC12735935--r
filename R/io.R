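#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving the affine; parameter maps are
#' written as float32 and label volumes as int16.
#'
#' @param x 3D/4D array (optionally an RNifti image).
#' @param path file path (.nii or .nii.gz).
#' @param datatype "float" (default) or "int16" for label volumes.
#' @return `write_volume` returns the path invisibly; `read_volume` returns
#'   an array with the NIfTI attributes attached.
#' @export
write_volume <- function(x, path, datatype = c("float", "int16")) {
  datatype <- match.arg(datatype)
  img <- RNifti::asNifti(x)
  RNifti::writeNifti(img, path,
                     datatype = if (datatype == "float") "float" else "short")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  RNifti::readNifti(path)
}

#' Write/read b-value and b-vector tables
#'
#' FSL dialect: the bval file holds one space-separated row of b-values;
#' the bvec file holds three space-separated rows (x, y, z components), one
#' column per volume.
#'
#' @param scheme an `acquisition_scheme`.
#' @param bval_path,bvec_path output paths.
#' @return paths invisibly.
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(scheme$bvals, collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, paste, collapse = " "), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bval_bvec
#' @param n_volumes expected volume count (e.g. the DWI 4th dimension);
#'   a mismatch raises an error.
#' @export
read_bval_bvec <- function(bval_path, bvec_path, n_volumes = NULL) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  if (length(rows) != 3) stopf("bvec file must have exactly 3 rows")
  if (length(unique(c(length(bvals), lengths(rows)))) != 1)
    stopf("bval/bvec column counts disagree")
  if (!is.null(n_volumes) && length(bvals) != n_volumes)
    stopf("bval/bvec columns (%d) must match volume count (%d)",
          length(bvals), n_volumes)
  list(bvals = bvals, bvecs = do.call(rbind, rows))
}

#' Serialize / restore a run configuration
#'
#' YAML round trip of the pipeline configuration (phantom, cohort, fit,
#' fusion and seed settings). `load_run_config(save_run_config(cfg))`
#' restores an identical list.
#'
#' @param config a named list.
#' @param path YAML file path.
#' @return the path / the restored list.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Default end-to-end run configuration
#'
#' Desk-scale defaults: a 24 HC / 19 mTBI cohort on a small grid with 90
#' contiguous parcels, the standard 14-shell acquisition, SNR 100, and
#' 3 RGCCA components per block.
#'
#' @param grid_shape voxel grid (smaller grids run faster).
#' @param n_hc,n_mtbi group sizes.
#' @param snr acquisition SNR.
#' @param k fusion components per block.
#' @param seed global seed.
#' @param include_gose include the GOS-E block and outcome analyses.
#' @return a named list.
#' @export
default_run_config <- function(grid_shape = c(16, 16, 8), n_hc = 24,
                               n_mtbi = 19, snr = 100, k = 3, seed = 42L,
                               include_gose = TRUE) {
  list(grid_shape = as.integer(grid_shape), n_hc = as.integer(n_hc),
       n_mtbi = as.integer(n_mtbi), snr = snr, k = as.integer(k),
       seed = as.integer(seed), include_gose = include_gose,
       n_regions = 90L, asl_pairs = 20L, asl_snr = 50)
}

#' Run the full synthetic pipeline end to end
#'
#' simulate -> fit IVIM -> quantify CBF -> extract ROI features -> fuse ->
#' group statistics (+ GOS-E correlations when enabled) -> test-retest ICC,
#' writing every table plus JSON run metadata into `out_dir`. Identical
#' config and seed produce identical numeric outputs.
#'
#' @param config list from [default_run_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param verbose print stage progress.
#' @return invisible list with all intermediate results (cohort, phantom,
#'   blocks, fusion, group_stats, gose_stats, icc).
#' @export
run_end_to_end <- function(config = default_run_config(), out_dir = NULL,
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  scheme <- build_acquisition_scheme()
  spec <- phantom_spec(grid_shape = config$grid_shape,
                       n_regions = config$n_regions, snr = config$snr,
                       seed = seed)
  cohort <- make_cohort(config$n_hc, config$n_mtbi, seed = seed)
  say("simulating phantom for %d subjects", nrow(cohort))
  ph <- generate_phantom(spec, cohort)
  cfg_fit <- triexp_config()
  consts <- asl_constants()
  metric_maps <- list(CBF = list(), F_p = list(), F_f = list(),
                      F_s = list(), D_s = list())
  for (s in seq_len(nrow(cohort))) {
    id <- cohort$id[s]
    dwi <- simulate_dwi(ph$subjects[[id]], scheme, snr = config$snr,
                        noise_model = "rician",
                        seed = child_seed(seed, 1000L + s))
    fit <- fit_triexp_volume(dwi, cfg_fit)
    asl <- simulate_asl(ph$subjects[[id]]$cbf, consts,
                        n_pairs = config$asl_pairs, snr = config$asl_snr,
                        seed = child_seed(seed, 2000L + s))
    cbf <- quantify_cbf(split_and_subtract(asl), asl$m0, consts)
    metric_maps$CBF[[id]] <- cbf$cbf
    metric_maps$F_p[[id]] <- fit$fp
    metric_maps$F_f[[id]] <- fit$ff
    metric_maps$F_s[[id]] <- fit$fs
    metric_maps$D_s[[id]] <- fit$ds
    say("subject %s fitted (%d/%d)", id, s, nrow(cohort))
  }
  say("assembling blocks")
  blocks <- lapply(names(metric_maps), function(mod)
    zscore_block(assemble_block(metric_maps[[mod]], ph$atlas, mod,
                                subject_ids = cohort$id)))
  names(blocks) <- names(metric_maps)
  say("fusing %d blocks", length(blocks))
  fusion <- fuse(blocks, k = config$k, seed = seed)
  score_mat <- as.matrix(fusion$scores[, -1, drop = FALSE])
  rownames(score_mat) <- fusion$scores$id
  group_stats <- compare_groups(score_mat, cohort$group)
  gose_stats <- NULL
  fusion_gose <- NULL
  if (isTRUE(config$include_gose)) {
    # GOS-E synthesized from the subject loadings of the leading IC so the
    # outcome carries a recoverable multimodal signal
    mtbi <- cohort$group == "mTBI"
    cohort$gose[mtbi] <- synthesize_gose(score_mat[mtbi, 1])
    gose_block <- zscore_block(block_matrix(
      matrix(cohort$gose[mtbi], ncol = 1,
             dimnames = list(cohort$id[mtbi], "gose")), "GOSE"))
    blocks_mtbi <- lapply(blocks, function(b)
      block_matrix(b$data[mtbi, , drop = FALSE], b$modality, zscored = TRUE))
    blocks_mtbi <- lapply(blocks_mtbi, zscore_block)
    fusion_gose <- fuse(c(blocks_mtbi, list(gose_block)), k = config$k,
                        seed = seed)
    gs <- as.matrix(fusion_gose$scores[, -1, drop = FALSE])
    gose_stats <- correlate_gose(gs, cohort$gose[mtbi])
  }
  say("test-retest ICC")
  retest_ids <- attr(cohort, "retest_ids")
  icc_res <- NULL
  if (length(retest_ids) >= 3) {
    v1 <- lapply(retest_ids, function(id) {
      a <- simulate_asl(ph$subjects[[id]]$cbf, consts,
                        n_pairs = config$asl_pairs, snr = config$asl_snr,
                        seed = child_seed(seed, 3000L + match(id, cohort$id)))
      quantify_cbf(split_and_subtract(a), a$m0, consts)$cbf
    })
    v2 <- lapply(retest_ids, function(id) {
      a <- simulate_asl(ph$subjects[[id]]$cbf, consts,
                        n_pairs = config$asl_pairs, snr = config$asl_snr,
                        seed = child_seed(seed, 4000L + match(id, cohort$id)))
      quantify_cbf(split_and_subtract(a), a$m0, consts)$cbf
    })
    icc_res <- icc_map(v1, v2, variant = "consistency")
  }
  result <- list(cohort = cohort, atlas = ph$atlas, blocks = blocks,
                 fusion = fusion, group_stats = group_stats,
                 fusion_gose = fusion_gose, gose_stats = gose_stats,
                 icc = icc_res, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(fusion$scores, file.path(out_dir, "ic_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(fusion$ave)),
                     file.path(out_dir, "ave_table.csv"))
    utils::write.csv(group_stats, file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)
    if (!is.null(gose_stats))
      utils::write.csv(gose_stats, file.path(out_dir, "gose_correlation.csv"),
                       row.names = FALSE)
    for (mod in names(blocks))
      utils::write.csv(as.data.frame(blocks[[mod]]$data),
                       file.path(out_dir, sprintf("block_%s.csv", mod)))
    meta <- list(seed = seed, config = config,
                 n_ic = fusion$n_ic,
                 n_ic_gose = if (!is.null(fusion_gose)) fusion_gose$n_ic else NULL,
                 icc_summary = if (!is.null(icc_res)) icc_res$summary else NULL)
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
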