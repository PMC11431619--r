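#' Hemodynamic response kernels for the BOLD simulator
#'
#' Builds a response kernel sampled at the acquisition interval `tr`.
#' Families:
#' \describe{
#'   \item{canonical}{double-gamma: a gamma density peaking at
#'     `peak_delay` s minus `undershoot_ratio` times a gamma density peaking
#'     at `undershoot_delay` s, scaled to unit peak.}
#'   \item{latency_shifted}{the canonical shape delayed by `shift` s.}
#'   \item{inverted}{the negated canonical shape (consistently negative
#'     responses, as reported for substantial parts of cortex).}
#'   \item{saturating}{the canonical shape followed, after convolution, by
#'     a pointwise saturating transform `saturation * tanh(x / saturation)`;
#'     responses to temporally close events are sub-additive by
#'     construction, violating linear-model additivity.}
#' }
#'
#' @param family Kernel family, see Details.
#' @param tr Sampling interval (repetition time), seconds.
#' @param duration Kernel support, seconds (default 32).
#' @param peak_delay,undershoot_delay Gamma shape parameters, seconds.
#' @param undershoot_ratio Relative undershoot amplitude.
#' @param shift Latency shift in seconds (latency_shifted family).
#' @param saturation Saturation ceiling in signal units (saturating family).
#' @return Object of class `response_kernel`: list with `values` (kernel
#'   samples at 0, tr, 2 tr, ...), `tr`, `family` and the parameters.
#' @export
response_kernel <- function(family = c("canonical", "latency_shifted",
                                       "inverted", "saturating"),
                            tr = 2, duration = 32,
                            peak_delay = 6, undershoot_delay = 16,
                            undershoot_ratio = 1 / 6,
                            shift = 2, saturation = 1) {
  family <- match.arg(family)
  stopifnot(tr > 0, duration > 0, is.finite(saturation), saturation > 0)
  grid <- seq(0, duration, by = tr)
  if (family == "latency_shifted") grid <- pmax(grid - shift, 0)
  h <- dgamma(grid, shape = peak_delay, rate = 1) -
    undershoot_ratio * dgamma(grid, shape = undershoot_delay, rate = 1)
  h <- h / max(abs(h))
  if (family == "inverted") h <- -h
  structure(list(values = h, tr = tr, family = family,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               undershoot_ratio = undershoot_ratio,
                               shift = shift, saturation = saturation)),
            class = "response_kernel")
}

#' Autocorrelated noise model
#'
#' Stationary AR(1) noise with marginal standard deviation `sd` and lag-1
#' autocorrelation `ar1`, plus an optional slow sinusoidal drift with a
#' uniformly random phase.  Runs are separate acquisitions, so noise is
#' drawn independently per run.
#'
#' @param sd Marginal noise standard deviation, signal units.
#' @param ar1 AR(1) coefficient, in \[0, 1) (stationarity).
#' @param drift_amplitude Amplitude of the low-frequency drift component.
#' @param drift_period Drift period, seconds.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sd = 1, ar1 = 0.3, drift_amplitude = 0,
                        drift_period = 128) {
  stopifnot(sd >= 0, ar1 >= 0, ar1 < 1, drift_amplitude >= 0,
            drift_period > 0)
  structure(list(sd = sd, ar1 = ar1, drift_amplitude = drift_amplitude,
                 drift_period = drift_period), class = "noise_model")
}

#' Ground-truth selectivity map for simulation
#'
#' Per-voxel response weights: `w_onset` is the amplitude of the response
#' to any event (presence response), and `w_dim1` / `w_dim2` the amplitudes
#' of the differential responses to the levels of each dimension (binary
#' levels are coded +1 / -1, so "selective" means responding differently to
#' the two levels, not merely responding).  A voxel's ground-truth class
#' follows from which weights are nonzero.
#'
#' @param grid Integer vector, the 3D grid dimensions.
#' @param w_dim1,w_dim2,w_onset Numeric arrays (or vectors recycled over
#'   the grid) of response weights.
#' @param mask Logical array of in-brain voxels (default all TRUE).
#' @return Object of class `ground_truth_map` with a `classes` array in
#'   `c("non_responsive", "non_selective", "dim1_selective",
#'   "dim2_selective")`.
#' @export
ground_truth_map <- function(grid, w_dim1 = 0, w_dim2 = 0, w_onset = 0,
                             mask = NULL) {
  expand <- function(w) array(w, dim = grid)
  w1 <- expand(w_dim1); w2 <- expand(w_dim2); w0 <- expand(w_onset)
  stopifnot(all(is.finite(w1)), all(is.finite(w2)), all(is.finite(w0)))
  if (is.null(mask)) mask <- array(TRUE, dim = grid)
  classes <- array("non_responsive", dim = grid)
  classes[w0 != 0] <- "non_selective"
  classes[w1 != 0] <- "dim1_selective"
  classes[w2 != 0] <- "dim2_selective"
  if (any(w1 != 0 & w2 != 0)) {
    stop("a voxel cannot be selective for both dimensions in the ground truth",
         call. = FALSE)
  }
  structure(list(grid = as.integer(grid), mask = mask,
                 w_dim1 = w1, w_dim2 = w2, w_onset = w0,
                 classes = classes),
            class = "ground_truth_map")
}

#' Ground truth with the four canonical voxel classes
#'
#' Convenience constructor laying out equal blocks of non-responsive,
#' responsive-but-non-selective, dimension-1-selective and
#' dimension-2-selective voxels on a small grid — one voxel population per
#' class, for validation studies.
#'
#' @param grid 3D grid dimensions (default `c(10, 10, 4)`).
#' @param amplitude Response amplitude for nonzero weights (signal units).
#' @return A `ground_truth_map`.
#' @export
example_truth <- function(grid = c(10, 10, 4), amplitude = 1) {
  nv <- prod(grid)
  cls <- rep(1:4, length.out = nv)  # interleaved so classes span the volume
  ground_truth_map(grid,
                   w_dim1 = amplitude * (cls == 3),
                   w_dim2 = amplitude * (cls == 4),
                   w_onset = amplitude * (cls != 1))
}

# ±1 level coding: first declared level -> +1, second -> -1; dimensions
# with k > 2 levels get centred equally spaced codes in [-1, 1].
level_codes <- function(levels) {
  k <- length(levels)
  codes <- if (k == 1) 0 else if (k == 2) c(1, -1) else seq(1, -1, length.out = k)
  setNames(codes, levels)
}

#' Per-voxel neural event drive for a schedule
#'
#' Maps each event to its acquisition frame and accumulates, per voxel,
#' `w_onset + code(dim1) * w_dim1 + code(dim2) * w_dim2`, where binary
#' dimension levels are coded +1 / -1.  This is the pre-hemodynamic input
#' to [synthesize_run()].
#'
#' @param schedule An `event_schedule`.
#' @param weights List with numeric vectors `w_onset`, `w_dim1`, `w_dim2`
#'   (one value per voxel).
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of acquired volumes.
#' @return `n_voxels x n_volumes` matrix of event drive.
#' @export
event_drive <- function(schedule, weights, tr, n_volumes) {
  if (max(schedule$onsets + schedule$durations) > n_volumes * tr + 1e-9) {
    stop("schedule extends beyond the acquisition window (n_volumes * tr)",
         call. = FALSE)
  }
  nv <- length(weights$w_onset)
  stopifnot(length(weights$w_dim1) == nv, length(weights$w_dim2) == nv)
  frames <- pmin(floor(schedule$onsets / tr) + 1L, n_volumes)
  dims <- names(schedule$dim_levels)
  c1 <- level_codes(schedule$dim_levels[[dims[1]]])[schedule$labels[[dims[1]]]]
  c2 <- level_codes(schedule$dim_levels[[dims[2]]])[schedule$labels[[dims[2]]]]
  drive <- matrix(0, nv, n_volumes)
  # events sharing a frame accumulate
  for (e in seq_along(frames)) {
    drive[, frames[e]] <- drive[, frames[e]] +
      weights$w_onset + c1[e] * weights$w_dim1 + c2[e] * weights$w_dim2
  }
  drive
}

# causal convolution of each row with the kernel, truncated to input length
convolve_rows <- function(drive, kernel_values) {
  n <- ncol(drive)
  t(apply(drive, 1, function(x) {
    convolve(x, rev(kernel_values), type = "open")[seq_len(n)]
  }))
}

# stationary AR(1) series with marginal sd `sd`, exact (no burn-in needed)
ar1_series <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Synthesize one run of voxel time series
#'
#' Convolves the event drive with the response kernel (for the saturating
#' family, applies the pointwise saturating transform after convolution)
#' and adds AR(1) noise and optional drift, independently per voxel.
#' Bit-reproducible for a given seed.
#'
#' @param drive `n_voxels x n_volumes` event-drive matrix from
#'   [event_drive()].
#' @param kernel A `response_kernel` (same `tr` as the drive).
#' @param noise A `noise_model`.
#' @param seed Optional integer seed.
#' @param baseline Constant signal offset (default 100, a typical
#'   raw-BOLD scale; irrelevant after standardization).
#' @return `n_voxels x n_volumes` matrix.
#' @export
synthesize_run <- function(drive, kernel, noise = noise_model(),
                           seed = NULL, baseline = 100) {
  stopifnot(inherits(kernel, "response_kernel"), inherits(noise, "noise_model"))
  signal <- convolve_rows(drive, kernel$values)
  if (kernel$family == "saturating") {
    s <- kernel$params$saturation
    signal <- s * tanh(signal / s)
  }
  nv <- nrow(signal); n <- ncol(signal)
  with_rng(seed, {
    if (noise$sd > 0) {
      for (v in seq_len(nv)) {
        signal[v, ] <- signal[v, ] + ar1_series(n, noise$ar1, noise$sd)
      }
    }
    if (noise$drift_amplitude > 0) {
      tt <- (seq_len(n) - 1) * kernel$tr
      for (v in seq_len(nv)) {
        phase <- runif(1, 0, 2 * pi)
        signal[v, ] <- signal[v, ] +
          noise$drift_amplitude * sin(2 * pi * tt / noise$drift_period + phase)
      }
    }
  })
  signal + baseline
}

#' Simulate a full four-run TWISTER acquisition
#'
#' For each run of the design, builds the per-voxel event drive from the
#' ground-truth weights, synthesizes the BOLD series, and embeds it in a 4D
#' array on the ground-truth grid.  Noise is drawn independently per run
#' from run-specific child seeds, so the whole dataset is reproducible from
#' one seed.
#'
#' @param design A `twister_design`.
#' @param truth A `ground_truth_map`.
#' @param kernel A `response_kernel` (its `tr` is the acquisition TR).
#' @param noise A `noise_model`.
#' @param seed Integer seed.
#' @param n_volumes Volumes per run (default `run_length / tr`).
#' @return Object of class `tca_simulation`: list with `runs` (named list
#'   of 4D arrays), `mask`, `truth`, `design`, `tr`, `n_volumes`.
#' @export
simulate_experiment <- function(design, truth, kernel = response_kernel(),
                                noise = noise_model(), seed = 1,
                                n_volumes = NULL) {
  tr <- kernel$tr
  if (is.null(n_volumes)) {
    n_volumes <- as.integer(round(design$runs$A1$run_length / tr))
  }
  idx <- which(truth$mask)
  weights <- list(w_onset = truth$w_onset[idx],
                  w_dim1 = truth$w_dim1[idx],
                  w_dim2 = truth$w_dim2[idx])
  runs <- vector("list", length(design$runs))
  names(runs) <- names(design$runs)
  for (i in seq_along(design$runs)) {
    key <- names(design$runs)[i]
    drive <- event_drive(design$runs[[key]], weights, tr, n_volumes)
    mat <- synthesize_run(drive, kernel, noise,
                          seed = child_seed(seed, 10 + i))
    vol <- array(0, dim = c(truth$grid, n_volumes))
    flat <- matrix(vol, nrow = prod(truth$grid))
    flat[idx, ] <- mat
    runs[[key]] <- array(flat, dim = c(truth$grid, n_volumes))
  }
  structure(list(runs = runs, mask = truth$mask, truth = truth,
                 design = design, tr = tr, n_volumes = n_volumes),
            class = "tca_simulation")
}
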