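#' Standardize runs per voxel and concatenate
#'
#' Each run segment is z-scored per voxel (population denominator, for
#' bit-reproducibility; Pearson correlations are unaffected) before
#' concatenation, so no run dominates the concatenated series through its
#' scale.  Voxels with (near-)zero variance in any segment are flagged
#' invalid rather than silently zeroed.
#'
#' @param runs List of `n_voxels x n_time` matrices (equal time length,
#'   same voxel order).
#' @param tol Variance tolerance below which a voxel is invalid.
#' @return List with `series` (`n_voxels x sum(n_time)` matrix) and
#'   `invalid` (logical vector; rows of invalid voxels are NA).
#' @export
standardize_runs <- function(runs, tol = 1e-12) {
  stopifnot(length(runs) >= 1)
  nv <- nrow(runs[[1]])
  lens <- vapply(runs, ncol, integer(1))
  if (any(vapply(runs, nrow, integer(1)) != nv)) {
    stop("all runs must share the voxel count", call. = FALSE)
  }
  invalid <- logical(nv)
  segs <- lapply(runs, function(m) {
    mu <- rowMeans(m)
    cen <- m - mu
    s <- sqrt(rowMeans(cen^2))
    invalid <<- invalid | !is.finite(s) | s < tol
    cen / s
  })
  series <- do.call(cbind, segs)
  series[invalid, ] <- NA_real_
  list(series = series, invalid = invalid)
}

#' Assemble the seed / red / blue role series
#'
#' Builds the three role-assigned series of the TCA analysis: the seed and
#' the red and blue references, each the concatenation of one or more
#' standardized per-run voxel series.  In the canonical four-run layout the
#' seed is \[A1, B2\], the red reference \[A2, B1\] (consistent with the
#' seed on dimension 1) and the blue reference \[B1, A2\] (consistent on
#' dimension 2).
#'
#' @param seed_runs,red_runs,blue_runs Lists of `n_voxels x n_time`
#'   matrices (one per constituent run, in concatenation order).
#' @param voxel_index Optional integer vector mapping rows to 3D grid
#'   indices (kept for map reconstruction).
#' @param grid Optional 3D grid dimensions.
#' @return Object of class `run_series_set`: `seed`, `red`, `blue`
#'   matrices, `N` (time points per concatenated series), `invalid`
#'   (union over the three roles), `voxel_index`, `grid`.
#' @export
run_series_set <- function(seed_runs, red_runs, blue_runs,
                           voxel_index = NULL, grid = NULL) {
  s <- standardize_runs(seed_runs)
  r <- standardize_runs(red_runs)
  b <- standardize_runs(blue_runs)
  if (ncol(s$series) != ncol(r$series) || ncol(s$series) != ncol(b$series)) {
    stop("seed, red and blue concatenations must have equal length",
         call. = FALSE)
  }
  invalid <- s$invalid | r$invalid | b$invalid
  structure(list(seed = s$series, red = r$series, blue = b$series,
                 N = ncol(s$series), invalid = invalid,
                 voxel_index = voxel_index, grid = grid),
            class = "run_series_set")
}

# row-wise Pearson correlation of two matrices with centred rows
row_cor <- function(a, b) {
  a <- a - rowMeans(a); b <- b - rowMeans(b)
  rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
}

#' Per-voxel correlation triple
#'
#' Pearson correlations between the three role series of every voxel:
#' seed-red (`r_sr`), seed-blue (`r_sb`) and red-blue (`r_rb`).  With
#' `clip_negative = TRUE` (the default) negative coefficients are set to 0,
#' restricting the analysis to asymmetries driven by positive consistency;
#' clipping can make the correlation matrix non-positive-semi-definite,
#' which the test stage handles explicitly (see [handle_non_psd()]).
#' `clip_rb = FALSE` restricts clipping to `r_sr` and `r_sb`.
#'
#' @param set A `run_series_set`.
#' @param clip_negative Clip negative correlations to zero (default TRUE).
#' @param clip_rb Whether clipping also applies to `r_rb` (default TRUE).
#' @return Object of class `correlation_triple`: data frame columns
#'   `r_sr`, `r_sb`, `r_rb` (clipped values) plus `raw_sr`, `raw_sb`,
#'   `raw_rb` and the `invalid` flag.
#' @export
correlation_triple <- function(set, clip_negative = TRUE, clip_rb = TRUE) {
  stopifnot(inherits(set, "run_series_set"))
  raw_sr <- row_cor(set$seed, set$red)
  raw_sb <- row_cor(set$seed, set$blue)
  raw_rb <- row_cor(set$red, set$blue)
  clip <- function(r, on) if (clip_negative && on) pmax(r, 0) else r
  out <- data.frame(r_sr = clip(raw_sr, TRUE), r_sb = clip(raw_sb, TRUE),
                    r_rb = clip(raw_rb, clip_rb),
                    raw_sr = raw_sr, raw_sb = raw_sb, raw_rb = raw_rb,
                    invalid = set$invalid)
  class(out) <- c("correlation_triple", class(out))
  out
}

#' Effective sample size of an autocorrelated series
#'
#' Estimates the number of effectively independent time points,
#' `ESS = N / (1 + 2 * sum_k ACF_k)`, from the sample autocorrelation
#' function.  The infinite sum is truncated by the initial-positive-
#' sequence rule (accumulate until the first non-positive sample ACF, the
#' standard practice for autocorrelation-time estimation) with a hard
#' maximum lag of `N / 4`; the estimate is capped at `N`.
#'
#' @param x Numeric series.
#' @param max_lag Maximum lag entering the sum (default `floor(N / 4)`).
#' @param min_length Shortest admissible series (default 30).
#' @return Scalar ESS in (0, N\].
#' @examples
#' set.seed(1)
#' estimate_ess(rnorm(1000))  # close to 1000 for white noise
#' @export
estimate_ess <- function(x, max_lag = NULL, min_length = 30) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < min_length) {
    stop(sprintf("series of length %d is shorter than the minimum %d",
                 n, min_length), call. = FALSE)
  }
  if (is.null(max_lag)) max_lag <- floor(n / 4)
  rho <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  s <- 0
  for (r in rho) {
    if (!is.finite(r) || r <= 0) break
    s <- s + r
  }
  min(n / (1 + 2 * s), n)
}

# 26-connected (radius-1) or larger cubic-neighbourhood median filter over
# masked voxels of a 3D volume; out-of-mask voxels neither contribute nor
# are filtered.
median_smooth_volume <- function(vol, mask, radius = 1) {
  d <- dim(vol)
  out <- vol
  idx <- which(mask, arr.ind = TRUE)
  off <- as.matrix(expand.grid(x = -radius:radius, y = -radius:radius,
                               z = -radius:radius))
  for (i in seq_len(nrow(idx))) {
    nb <- sweep(off, 2, idx[i, ], `+`)
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[keep, , drop = FALSE]
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    lin <- lin[mask[lin]]
    vals <- vol[lin]
    vals <- vals[is.finite(vals)]
    if (length(vals)) out[idx[i, , drop = FALSE]] <- median(vals)
  }
  out
}

#' Voxel-wise effective sample size map
#'
#' Computes one ESS estimate per role series (seed, red, blue) and voxel,
#' averages the three, and applies robust spatial smoothing — a median
#' filter over the cubic in-mask neighbourhood — to reduce random
#' variation using neighbouring voxels' estimates.  Voxels whose smoothed
#' ESS does not exceed `min_ess` are flagged invalid (the test downstream
#' needs positive degrees of freedom, df = ESS - 3).
#'
#' @param set A `run_series_set` carrying `voxel_index` and `grid` (both
#'   required for smoothing; without them the unsmoothed average is
#'   returned with a warning-free passthrough, radius 0).
#' @param radius Neighbourhood radius in voxels (default 1, the
#'   26-connected neighbourhood); 0 disables smoothing.
#' @param min_ess Validity floor (default 4).
#' @return List with per-role matrices column-bound in `per_role`,
#'   `averaged`, `smoothed` (vectors over voxels) and `invalid`.
#' @export
ess_map <- function(set, radius = 1, min_ess = 4) {
  stopifnot(inherits(set, "run_series_set"))
  nv <- nrow(set$seed)
  roles <- list(seed = set$seed, red = set$red, blue = set$blue)
  per_role <- vapply(roles, function(m) {
    vapply(seq_len(nv), function(v) {
      if (set$invalid[v]) return(NA_real_)
      estimate_ess(m[v, ])
    }, numeric(1))
  }, numeric(nv))
  per_role <- matrix(per_role, nrow = nv,
                     dimnames = list(NULL, names(roles)))
  averaged <- rowMeans(per_role)
  smoothed <- averaged
  if (radius > 0 && !is.null(set$grid) && !is.null(set$voxel_index)) {
    vol <- array(NA_real_, dim = set$grid)
    maskvol <- array(FALSE, dim = set$grid)
    maskvol[set$voxel_index] <- !set$invalid
    vol[set$voxel_index] <- averaged
    sm <- median_smooth_volume(vol, maskvol, radius)
    smoothed <- sm[set$voxel_index]
    smoothed[set$invalid] <- NA_real_
  }
  invalid <- set$invalid | !is.finite(smoothed) | smoothed <= min_ess
  list(per_role = per_role, averaged = averaged, smoothed = smoothed,
       invalid = invalid)
}
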