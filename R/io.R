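#' Write an event schedule as a BIDS-style events.tsv
#'
#' Tab-separated, header row `onset`, `duration`, then one column per
#' experimental dimension; onsets and durations printed at millisecond
#' precision so files are byte-identical across writes.
#'
#' @param schedule An `event_schedule`.
#' @param path Output file path.
#' @export
write_events <- function(schedule, path) {
  df <- data.frame(onset = sprintf("%.3f", schedule$onsets),
                   duration = sprintf("%.3f", schedule$durations),
                   schedule$labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a BIDS-style events.tsv into an event schedule
#'
#' @param path File path.
#' @param dim_levels Optional named list of level vectors; inferred from
#'   the observed labels (sorted) when absent.
#' @param run_length Run duration in seconds; defaults to the last event's
#'   end.
#' @return An `event_schedule`.
#' @export
read_events <- function(path, dim_levels = NULL, run_length = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("onset", "duration") %in% names(df))) {
    stop(sprintf("%s: events file must have 'onset' and 'duration' columns",
                 path), call. = FALSE)
  }
  dims <- setdiff(names(df), c("onset", "duration"))
  labels <- df[, dims, drop = FALSE]
  if (is.null(dim_levels)) {
    dim_levels <- lapply(labels, function(x) sort(unique(x)))
  }
  if (is.null(run_length)) {
    run_length <- max(df$onset + df$duration)
  }
  new_event_schedule(df$onset, df$duration, labels, dim_levels, run_length)
}

#' Write a TWISTER design to disk
#'
#' One events.tsv per run (`<prefix><key>_events.tsv`) plus a JSON
#' manifest (`<prefix>design.json`) recording the seed, dimensions, level
#' sets, generating parameters and any sub-run split structure.  Output is
#' deterministic: identical designs produce byte-identical files.
#'
#' @param design A `twister_design`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix (default `""`).
#' @return Invisibly, the manifest path.
#' @export
write_design <- function(design, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(design$runs)) {
    write_events(design$runs[[key]],
                 file.path(dir, sprintf("%s%s_events.tsv", prefix, key)))
  }
  manifest <- list(
    seed = design$seed,
    dimension_names = design$dimension_names,
    dim_levels = design$runs$A1$dim_levels,
    run_keys = names(design$runs),
    mode = design$mode,
    params = design$params,
    split = design$split)
  path <- file.path(dir, paste0(prefix, "design.json"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}

#' Read a TWISTER design written by [write_design()]
#'
#' @param dir Directory holding the events files and manifest.
#' @param prefix Filename prefix used at write time.
#' @return A `twister_design`.
#' @export
read_design <- function(dir, prefix = "") {
  manifest <- jsonlite::fromJSON(file.path(dir, paste0(prefix, "design.json")),
                                 simplifyVector = TRUE)
  dim_levels <- lapply(manifest$dim_levels, as.character)
  runs <- lapply(setNames(nm = manifest$run_keys), function(key) {
    read_events(file.path(dir, sprintf("%s%s_events.tsv", prefix, key)),
                dim_levels = dim_levels,
                run_length = manifest$params$run_length)
  })
  structure(list(runs = runs, dimension_names = manifest$dimension_names,
                 seed = manifest$seed, split = manifest$split,
                 mode = manifest$mode, params = manifest$params),
            class = "twister_design")
}

#' Validate on-disk design files against the TWISTER invariants
#'
#' Reads the four events files and the manifest, reconstructs the design
#' and runs every structural check ([validate_design()]) plus file-level
#' checks (parseability, onset synchronization at 1 ms).  Violations are
#' reported, not raised.
#'
#' @param dir Directory holding the design files.
#' @param prefix Filename prefix.
#' @return List `valid`, `violations` (character vector naming run, event
#'   and dimension for each problem).
#' @export
validate_design_files <- function(dir, prefix = "") {
  design <- tryCatch(read_design(dir, prefix), error = function(e) e)
  if (inherits(design, "error")) {
    return(list(valid = FALSE,
                violations = paste("unreadable design:",
                                   conditionMessage(design))))
  }
  validate_design(design)
}

#' Load preprocessed 4D NIfTI runs under a mask
#'
#' Reads each run, checks that all runs and the mask share grid shape and
#' affine and that all runs have the same number of volumes, and extracts
#' the masked voxel-by-time matrices.
#'
#' @param paths Character vector of 4D NIfTI paths.
#' @param mask_path 3D NIfTI mask path (nonzero = in mask).
#' @return List `runs` (list of `n_voxels x n_volumes` matrices), `mask`
#'   (logical array), `voxel_index` (linear indices into the grid),
#'   `grid`, `template` (mask image, for writing maps back).
#' @export
load_runs <- function(paths, mask_path) {
  mask_img <- RNifti::readNifti(mask_path)
  mask <- array(as.logical(mask_img != 0), dim = dim(mask_img)[1:3])
  grid <- dim(mask)
  idx <- which(mask)
  runs <- vector("list", length(paths))
  n_vol <- NULL
  bad <- character(0)
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    d <- dim(img)
    if (length(d) != 4 || !identical(d[1:3], as.integer(grid))) {
      bad <- c(bad, sprintf("%s: grid %s does not match mask grid %s",
                            paths[i], paste(d, collapse = "x"),
                            paste(grid, collapse = "x")))
      next
    }
    if (max(abs(RNifti::xform(img)[1:3, ] -
                RNifti::xform(mask_img)[1:3, ])) > 1e-4) {
      bad <- c(bad, sprintf("%s: affine does not match the mask affine",
                            paths[i]))
      next
    }
    if (is.null(n_vol)) n_vol <- d[4]
    if (d[4] != n_vol) {
      bad <- c(bad, sprintf("%s: %d volumes, expected %d", paths[i], d[4],
                            n_vol))
      next
    }
    flat <- matrix(img, nrow = prod(grid))
    runs[[i]] <- flat[idx, , drop = FALSE]
  }
  if (length(bad)) {
    stop(paste(c("run loading failed:", bad), collapse = "\n  "),
         call. = FALSE)
  }
  names(runs) <- tools::file_path_sans_ext(basename(paths), compression = TRUE)
  list(runs = runs, mask = mask, voxel_index = idx, grid = grid,
       template = mask_img)
}

# embed a per-voxel vector into a 3D volume (zero outside the mask)
vector_to_volume <- function(values, grid, voxel_index, fill = 0) {
  vol <- array(fill, dim = grid)
  vol[voxel_index] <- ifelse(is.finite(values), values, fill)
  vol
}

#' Write TCA statistical maps and the summary table
#'
#' Emits one 3D NIfTI per statistic (t, df, p, q, ESS, class codes), a
#' signed t map thresholded at the uncorrected display threshold
#' (positive = red-selective), and a TSV summary over valid voxels with
#' 0-based array indices, world-space mm coordinates, the correlation
#' triple, ESS, test values and class.  Out-of-mask and invalid voxels
#' are written as zero in the volumes.
#'
#' @param result A `tca_result` (see [tca_pipeline()]).
#' @param out_dir Output directory.
#' @param display_p_threshold Uncorrected display threshold (default
#'   0.001).
#' @return Invisibly, the named vector of written paths.
#' @export
write_stat_maps <- function(result, out_dir, display_p_threshold = 0.001) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- result$grid; idx <- result$voxel_index
  class_code <- match(result$class, c("non_responsive", "non_selective",
                                      "red_selective", "blue_selective"))
  t_thresh <- ifelse(!is.na(result$p) & result$p < display_p_threshold,
                     result$t, 0)
  vols <- list(t = result$t, df = result$df, p = result$p, q = result$q,
               ess = result$ess, class = class_code,
               t_thresholded = t_thresh)
  paths <- character(0)
  for (nm in names(vols)) {
    vol <- vector_to_volume(vols[[nm]], grid, idx)
    img <- RNifti::asNifti(vol, reference = result$template)
    path <- file.path(out_dir, paste0("tca_", nm, ".nii.gz"))
    img <- RNifti::`pixdim<-`(img, RNifti::pixdim(result$template)[1:3])
    attr(img, "statistic") <- nm
    RNifti::writeNifti(img, path, datatype = "float")
    paths[nm] <- path
  }
  # summary table over valid voxels
  keep <- which(result$valid)
  coords <- arrayInd(idx[keep], grid)
  xf <- if (!is.null(result$template)) RNifti::xform(result$template)
        else diag(4)
  world <- t(xf %*% rbind(t(coords - 1), 1))[, 1:3, drop = FALSE]
  tab <- data.frame(i = coords[, 1] - 1L, j = coords[, 2] - 1L,
                    k = coords[, 3] - 1L,
                    x_mm = world[, 1], y_mm = world[, 2], z_mm = world[, 3],
                    r_sr = result$triple$r_sr[keep],
                    r_sb = result$triple$r_sb[keep],
                    r_rb = result$triple$r_rb[keep],
                    ess = result$ess[keep], t = result$t[keep],
                    df = result$df[keep], p = result$p[keep],
                    q = result$q[keep], class = result$class[keep])
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], signif, 6)
  tsv <- file.path(out_dir, "tca_summary.tsv")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["summary"] <- tsv
  invisible(paths)
}

#' Write a simulated dataset to disk
#'
#' One 4D NIfTI per run, the 3D mask, a ground-truth class-code map
#' (1 = non-responsive ... 4 = dimension-2-selective), the design events
#' files and manifest.  TR and voxel size are recorded in the headers.
#'
#' @param sim A `tca_simulation` from [simulate_experiment()].
#' @param dir Output directory.
#' @param voxel_size Isotropic voxel size in mm (default 3.5).
#' @return Invisibly, a named list of paths.
#' @export
write_simulation <- function(sim, dir, voxel_size = 3.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (key in names(sim$runs)) {
    img <- RNifti::asNifti(sim$runs[[key]])
    img <- RNifti::`pixdim<-`(img, c(rep(voxel_size, 3), sim$tr))
    p <- file.path(dir, sprintf("run_%s.nii.gz", key))
    RNifti::writeNifti(img, p, datatype = "float")
    paths[[key]] <- p
  }
  mask_img <- RNifti::asNifti(array(as.integer(sim$mask),
                                    dim = dim(sim$mask)))
  mask_img <- RNifti::`pixdim<-`(mask_img, rep(voxel_size, 3))
  paths$mask <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(mask_img, paths$mask, datatype = "uint8")
  cls <- array(match(sim$truth$classes,
                     c("non_responsive", "non_selective",
                       "dim1_selective", "dim2_selective")),
               dim = dim(sim$truth$classes))
  cls_img <- RNifti::asNifti(cls)
  cls_img <- RNifti::`pixdim<-`(cls_img, rep(voxel_size, 3))
  paths$truth <- file.path(dir, "truth_classes.nii.gz")
  RNifti::writeNifti(cls_img, paths$truth, datatype = "uint8")
  paths$design <- write_design(sim$design, dir)
  invisible(paths)
}

#' Read an analysis configuration
#'
#' YAML file with run paths and role assignment (`seed`, `red`, `blue`:
#' ordered lists of run file paths), `mask`, `tr`, optional `out_dir`,
#' `seed` (RNG) and any of the analysis keys (`clip_negative`, `clip_rb`,
#' `non_psd_policy`, `sidedness`, `q_threshold`, `display_p_threshold`,
#' `smoothing_radius`, `r_threshold`).  Unspecified keys take the
#' documented defaults; role sets must be disjoint.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(clip_negative = TRUE, clip_rb = TRUE,
                   non_psd_policy = "invalidate", sidedness = "two",
                   q_threshold = 0.05, display_p_threshold = 0.001,
                   smoothing_radius = 1, r_threshold = 0.1,
                   out_dir = "tca_out", seed = 1)
  cfg <- modifyList(defaults, cfg)
  for (role in c("seed", "red", "blue")) {
    if (is.null(cfg$roles[[role]]) || !length(cfg$roles[[role]])) {
      stop(sprintf("config: role '%s' must list at least one run", role),
           call. = FALSE)
    }
  }
  all_runs <- unlist(cfg$roles)
  if (anyDuplicated(all_runs)) {
    # the same acquisition may appear in red and blue concatenations in
    # different order, but seed runs must not re-appear as references
    dup <- intersect(cfg$roles$seed, c(cfg$roles$red, cfg$roles$blue))
    if (length(dup)) {
      stop(sprintf("config: seed runs also assigned as references: %s",
                   paste(dup, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(cfg$tr) || cfg$tr <= 0) {
    stop("config: 'tr' must be a positive number of seconds", call. = FALSE)
  }
  cfg
}

#' Write a machine-readable provenance record
#'
#' JSON log with the configuration (and its hash), RNG seed, package
#' version, timestamped-free deterministic content, and counts of voxels
#' excluded by reason — enough to reproduce and audit a run.
#'
#' @param cfg Configuration list.
#' @param counts Named list of diagnostic counts.
#' @param path Output path.
#' @export
write_provenance <- function(cfg, counts, path) {
  rec <- list(
    package = "twistca",
    version = as.character(utils::packageVersion("twistca")),
    config = cfg,
    config_hash = substr(digest_hash(cfg), 1, 16),
    counts = counts)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}

# content hash without external dependencies: md5 of the serialized object
digest_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
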