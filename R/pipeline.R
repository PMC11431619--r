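#' Run the full TCA analysis on in-memory run matrices
#'
#' The complete voxel-wise procedure: per-run standardization and
#' role-series concatenation, the correlation triple (with optional
#' negative-correlation clipping), effective-sample-size estimation
#' (per role series, averaged, robustly smoothed), the Hotelling-Williams
#' test at df = ESS - 3 with the configured non-PSD policy, two-sided p
#' values, Benjamini-Hochberg FDR and voxel classification.
#'
#' @param seed_runs,red_runs,blue_runs Lists of `n_voxels x n_time`
#'   matrices, in concatenation order.
#' @param voxel_index,grid Optional geometry (linear in-mask indices and
#'   3D grid) enabling spatial ESS smoothing and map writing.
#' @param template Optional NIfTI image supplying header/affine for
#'   outputs.
#' @param clip_negative,clip_rb Clipping configuration (see
#'   [correlation_triple()]).
#' @param non_psd_policy Policy for inconsistent clipped triples (see
#'   [handle_non_psd()]).
#' @param sidedness p-value sidedness (see [p_from_t()]).
#' @param q_threshold FDR threshold.
#' @param smoothing_radius ESS median-smoothing radius in voxels.
#' @param r_threshold Responsiveness threshold for classification.
#' @return Object of class `tca_result`: list with per-voxel vectors
#'   `t`, `df`, `p`, `q`, `ess`, `valid`, `class`, `survives`, `method`,
#'   the `triple`, geometry (`grid`, `voxel_index`, `template`) and
#'   diagnostic `counts`.
#' @export
tca_pipeline <- function(seed_runs, red_runs, blue_runs,
                         voxel_index = NULL, grid = NULL, template = NULL,
                         clip_negative = TRUE, clip_rb = TRUE,
                         non_psd_policy = "invalidate",
                         sidedness = "two", q_threshold = 0.05,
                         smoothing_radius = 1, r_threshold = 0.1) {
  set <- run_series_set(seed_runs, red_runs, blue_runs,
                        voxel_index = voxel_index, grid = grid)
  triple <- correlation_triple(set, clip_negative = clip_negative,
                               clip_rb = clip_rb)
  ess <- ess_map(set, radius = smoothing_radius)
  res <- handle_non_psd(triple, ess$smoothed, policy = non_psd_policy)
  res$valid <- res$valid & !ess$invalid
  res$p[!res$valid] <- NA_real_
  pv <- p_from_t(res$t, res$df, sided = sidedness)
  res$p <- ifelse(res$valid, pv$p, NA_real_)
  fdr <- fdr_correct(res$p, q_threshold)
  result <- list(t = res$t, df = res$df, p = res$p, q = fdr$q,
                 survives = fdr$survives, ess = ess$smoothed,
                 valid = res$valid, method = res$method,
                 triple = triple,
                 grid = grid, voxel_index = voxel_index,
                 template = template)
  result$class <- classify_voxels(triple, c(result, list(q = fdr$q)),
                                  r_threshold = r_threshold)
  result$counts <- list(
    n_voxels = length(res$t),
    n_valid = sum(res$valid),
    n_zero_variance = sum(set$invalid),
    n_low_ess = sum(ess$invalid & !set$invalid),
    n_non_psd = res$n_non_psd,
    n_fdr_survivors = sum(fdr$survives),
    class_counts = as.list(table(result$class)))
  class(result) <- "tca_result"
  result
}

#' @export
print.tca_result <- function(x, ...) {
  cat(sprintf("tca_result: %d voxels, %d valid, %d FDR survivors\n",
              x$counts$n_voxels, x$counts$n_valid,
              x$counts$n_fdr_survivors))
  cc <- x$counts$class_counts
  if (length(cc)) {
    cat("  classes:", paste(sprintf("%s=%d", names(cc), unlist(cc)),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the TCA pipeline from a configuration file
#'
#' Loads the runs and mask named in the YAML configuration, assembles the
#' role series in the configured order, runs [tca_pipeline()], writes the
#' statistical maps, summary table and provenance log to the output
#' directory, and returns the result.
#'
#' @param config Path to a YAML configuration (see [read_config()]) or an
#'   equivalent list.
#' @return A `tca_result`, invisibly.
#' @export
run_tca <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  all_paths <- unique(unlist(cfg$roles))
  loaded <- load_runs(all_paths, cfg$mask)
  pick <- function(paths) {
    loaded$runs[match(paths, all_paths)]
  }
  result <- tca_pipeline(
    pick(cfg$roles$seed), pick(cfg$roles$red), pick(cfg$roles$blue),
    voxel_index = loaded$voxel_index, grid = loaded$grid,
    template = loaded$template,
    clip_negative = cfg$clip_negative, clip_rb = cfg$clip_rb,
    non_psd_policy = cfg$non_psd_policy, sidedness = cfg$sidedness,
    q_threshold = cfg$q_threshold,
    smoothing_radius = cfg$smoothing_radius,
    r_threshold = cfg$r_threshold)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stat_maps(result, cfg$out_dir,
                  display_p_threshold = cfg$display_p_threshold)
  write_provenance(cfg, result$counts,
                   file.path(cfg$out_dir, "provenance.json"))
  invisible(result)
}
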