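#' Randomly disperse event onsets along a run
#'
#' Draws `n_events` onset times uniformly over all feasible schedules of a
#' run of `run_length` seconds, subject to a minimum onset-to-onset
#' separation.  The sampler draws `n_events` uniform points on the interval
#' shrunk by the total minimum-gap budget, sorts them, and adds back the
#' cumulative gaps, which is exactly uniform over the feasible set.
#' Onsets are quantized to 1 ms so schedules serialize bit-exactly.
#'
#' @param n_events Number of events.
#' @param run_length Run duration in seconds.
#' @param min_separation Minimum allowed difference between consecutive
#'   onsets, seconds.  Must be positive.
#' @param duration Event duration in seconds (every event must end within
#'   the run).
#' @param seed Optional integer seed; a given seed reproduces the onsets
#'   bit-exactly.
#' @return Numeric vector of strictly increasing onset times in seconds.
#' @examples
#' on <- generate_onsets(120, 270, 0.5, seed = 1)
#' all(diff(on) >= 0.5)
#' @export
generate_onsets <- function(n_events, run_length, min_separation,
                            duration = 0, seed = NULL) {
  stopifnot(n_events >= 1, run_length > 0, min_separation > 0, duration >= 0)
  if (n_events * min_separation >= run_length) {
    stop(sprintf(
      "infeasible schedule: n_events * min_separation = %g s does not fit in run_length = %g s",
      n_events * min_separation, run_length), call. = FALSE)
  }
  slack <- run_length - duration - (n_events - 1) * min_separation
  if (slack <= 0) {
    stop(sprintf(
      "infeasible schedule: %d events of %g s with %g s separation exceed run_length = %g s",
      n_events, duration, min_separation, run_length), call. = FALSE)
  }
  u <- with_rng(seed, sort(runif(n_events, 0, slack)))
  onsets <- round(u + (seq_len(n_events) - 1) * min_separation, 3)
  onsets
}

#' Construct an event schedule with labelled events
#'
#' Assigns each event one level on each experimental dimension, optionally
#' balanced so every level appears equally often per dimension.  The result
#' is the reference run of a TWISTER design (conventionally A1).
#'
#' @param onsets Strictly increasing onset times, seconds (see
#'   [generate_onsets()]).
#' @param dim_levels Named list of two character vectors, the levels of each
#'   experimental dimension (each with at least 2 levels, except in the
#'   degenerate single-level case used for testing).
#' @param duration Event duration in seconds (scalar, recycled).
#' @param run_length Run duration in seconds.
#' @param balance If `TRUE` (default), each level appears exactly
#'   `n_events / n_levels` times per dimension; requires divisibility.
#' @param seed Optional integer seed for the label shuffles.
#' @return An object of class `event_schedule`: a list with elements
#'   `onsets`, `durations`, `labels` (data frame, one column per dimension),
#'   `dim_levels`, `run_length`.
#' @export
assign_labels <- function(onsets, dim_levels, duration = 0.5,
                          run_length = max(onsets) + duration,
                          balance = TRUE, seed = NULL) {
  n <- length(onsets)
  if (is.null(names(dim_levels)) || any(!nzchar(names(dim_levels)))) {
    names(dim_levels) <- paste0("dim", seq_along(dim_levels))
  }
  labels <- with_rng(seed, {
    as.data.frame(lapply(dim_levels, function(levels) {
      k <- length(levels)
      if (balance) {
        if (n %% k != 0) {
          stop(sprintf(
            "balanced assignment impossible: %d events not divisible by %d levels",
            n, k), call. = FALSE)
        }
        sample(rep(levels, each = n %/% k))
      } else {
        sample(levels, n, replace = TRUE)
      }
    }), stringsAsFactors = FALSE)
  })
  new_event_schedule(onsets, rep(duration, n), labels, dim_levels, run_length)
}

new_event_schedule <- function(onsets, durations, labels, dim_levels,
                               run_length) {
  sched <- structure(
    list(onsets = as.numeric(onsets), durations = as.numeric(durations),
         labels = labels, dim_levels = dim_levels,
         run_length = as.numeric(run_length)),
    class = "event_schedule")
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched, min_separation = NULL) {
  with(sched, {
    if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
    if (!is.null(min_separation) && any(diff(onsets) < min_separation - 1e-9)) {
      stop("onset separation below the configured minimum")
    }
    if (any(onsets + durations > run_length + 1e-9)) {
      stop("events extend beyond run_length")
    }
    if (nrow(labels) != length(onsets)) stop("one label row per event required")
    for (d in names(dim_levels)) {
      if (!all(labels[[d]] %in% dim_levels[[d]])) {
        stop(sprintf("labels on dimension '%s' outside declared levels", d))
      }
    }
  })
  invisible(sched)
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("event_schedule: %d events over %g s\n",
              length(x$onsets), x$run_length))
  for (d in names(x$dim_levels)) {
    tab <- table(factor(x$labels[[d]], levels = x$dim_levels[[d]]))
    cat(sprintf("  %s: %s\n", d,
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

# Draw a uniformly random derangement (fixed-point-free permutation) of
# 1..k by rejection; for k = 2 this is deterministically the swap.
random_derangement <- function(k) {
  if (k < 2) stop("a derangement needs at least 2 levels", call. = FALSE)
  if (k == 2) return(c(2L, 1L))
  repeat {
    p <- sample.int(k)
    if (!any(p == seq_len(k))) return(p)
  }
}

#' Twist an event schedule along one or both dimensions
#'
#' Produces a new schedule with identical onsets and durations whose labels
#' on the twisted dimensions are changed event-by-event: `invert` swaps the
#' two levels of a binary dimension (guaranteeing maximal inconsistency),
#' `permute` applies a uniformly drawn fixed-point-free relabelling of the
#' levels (required for dimensions with more than two levels).
#'
#' @param schedule An `event_schedule`.
#' @param dimensions Dimensions to twist: indices or names.
#' @param mode `"invert"` (binary dimensions only) or `"permute"`.
#' @param seed Optional seed for the permute mode.
#' @return A twisted `event_schedule`.
#' @examples
#' s <- assign_labels(generate_onsets(8, 30, 0.5, seed = 1),
#'                    list(shape = c("square", "circle"),
#'                         colour = c("red", "green")), seed = 1)
#' identical(twist(twist(s, 1), 1)$labels, s$labels)  # involution
#' @export
twist <- function(schedule, dimensions, mode = c("invert", "permute"),
                  seed = NULL) {
  mode <- match.arg(mode)
  dims <- if (is.numeric(dimensions)) names(schedule$dim_levels)[dimensions]
          else dimensions
  if (any(is.na(dims)) || !all(dims %in% names(schedule$dim_levels))) {
    stop("unknown dimension in 'dimensions'", call. = FALSE)
  }
  labels <- schedule$labels
  with_rng(seed, {
    for (d in dims) {
      levels <- schedule$dim_levels[[d]]
      k <- length(levels)
      if (mode == "invert") {
        if (k != 2) {
          stop(sprintf(
            "dimension '%s' has %d levels; 'invert' needs a binary dimension, use mode = \"permute\"",
            d, k), call. = FALSE)
        }
        map <- setNames(rev(levels), levels)
      } else {
        map <- setNames(levels[random_derangement(k)], levels)
      }
      labels[[d]] <- unname(map[labels[[d]]])
    }
  })
  new_event_schedule(schedule$onsets, schedule$durations, labels,
                     schedule$dim_levels, schedule$run_length)
}

#' Build a four-run TWISTER design
#'
#' Generates the reference run A1 by randomly dispersing events and
#' assigning balanced labels, then derives B1 (twisted on dimension 1),
#' A2 (twisted on dimension 2) and B2 (twisted on both).  All four runs
#' share identical onsets and durations; only labels differ.  Runs may
#' optionally be split into equal-duration sub-runs whose seeded
#' presentation order is recorded in the design (the schedules themselves
#' stay in canonical order, so the split never alters label content).
#'
#' @param n_events Events per run (default 120).
#' @param run_length Run duration in seconds (default 270, i.e. 4:30 min).
#' @param min_separation Minimum onset separation, seconds (default 0.5).
#' @param duration Event duration, seconds (default 0.5).
#' @param dim_levels Named list of two level vectors (default a binary
#'   visual-category by action design).
#' @param mode Twisting mode, `"invert"` (default, binary dimensions) or
#'   `"permute"`.
#' @param split Optional number of sub-runs (2 or 3) per run; default no
#'   splitting.
#' @param seed Integer seed governing every random choice in the design.
#' @return Object of class `twister_design`: list with `runs` (named list
#'   `A1`, `B1`, `A2`, `B2` of `event_schedule`s), `dimension_names`,
#'   `seed`, `split` (NULL or list with `n_subruns`, `boundaries`,
#'   `presentation_order`), and the generating parameters.
#' @export
build_design <- function(n_events = 120, run_length = 270,
                         min_separation = 0.5, duration = 0.5,
                         dim_levels = list(category = c("face", "house"),
                                           action = c("left", "right")),
                         mode = c("invert", "permute"),
                         split = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (length(dim_levels) != 2) {
    stop("a TWISTER design twists exactly two dimensions", call. = FALSE)
  }
  onsets <- generate_onsets(n_events, run_length, min_separation,
                            duration, seed = child_seed(seed, 1))
  A1 <- assign_labels(onsets, dim_levels, duration, run_length,
                      balance = TRUE, seed = child_seed(seed, 2))
  B1 <- twist(A1, 1, mode, seed = child_seed(seed, 3))
  A2 <- twist(A1, 2, mode, seed = child_seed(seed, 4))
  B2 <- twist(twist(A1, 1, mode, seed = child_seed(seed, 3)),
              2, mode, seed = child_seed(seed, 4))
  split_info <- NULL
  if (!is.null(split)) {
    split <- as.integer(split)
    if (split < 2 || split > 3) stop("'split' must be 2 or 3", call. = FALSE)
    boundaries <- run_length * seq_len(split - 1) / split
    order <- with_rng(child_seed(seed, 5),
                      lapply(setNames(nm = c("A1", "B1", "A2", "B2")),
                             function(k) sample.int(split)))
    split_info <- list(n_subruns = split, boundaries = boundaries,
                       presentation_order = order)
  }
  structure(
    list(runs = list(A1 = A1, B1 = B1, A2 = A2, B2 = B2),
         dimension_names = names(A1$dim_levels),
         seed = seed, split = split_info, mode = mode,
         params = list(n_events = n_events, run_length = run_length,
                       min_separation = min_separation, duration = duration)),
    class = "twister_design")
}

#' @export
print.twister_design <- function(x, ...) {
  cat(sprintf("twister_design: 4 runs x %d events, %g s, dimensions [%s], seed %s\n",
              length(x$runs$A1$onsets), x$runs$A1$run_length,
              paste(x$dimension_names, collapse = ", "),
              format(x$seed)))
  invisible(x)
}

#' Per-dimension agreement matrix of a design
#'
#' Fraction of events on which each pair of runs carries the same label on
#' `dimension`.  For a valid design this is the two-by-two factorial
#' pattern: on dimension 1, A pairs with A and B with B (agreement 1) and
#' all cross pairs disagree on every event (agreement 0); on dimension 2
#' the 1/2 index plays that role.
#'
#' @param design A `twister_design`.
#' @param dimension Dimension index or name.
#' @return 4 x 4 numeric matrix with run-key dimnames.
#' @export
agreement_matrix <- function(design, dimension) {
  d <- if (is.numeric(dimension)) design$dimension_names[dimension]
       else dimension
  keys <- names(design$runs)
  m <- matrix(NA_real_, 4, 4, dimnames = list(keys, keys))
  for (i in keys) for (j in keys) {
    m[i, j] <- mean(design$runs[[i]]$labels[[d]] ==
                    design$runs[[j]]$labels[[d]])
  }
  m
}

#' Check every TWISTER design invariant
#'
#' Verifies shared timing across the four runs, per-run schedule validity,
#' and the factorial agreement structure: A1/A2 and B1/B2 agree on
#' dimension 1 and (for invert mode) disagree event-by-event with the other
#' two runs, and symmetrically for dimension 2.  For permute mode,
#' "non-identical" is checked as: no event keeps its label on a twisted
#' dimension.
#'
#' @param design A `twister_design` (or the list-of-runs equivalent read
#'   from disk).
#' @return List with `valid` (logical) and `violations` (character vector;
#'   each entry names the run, event and dimension concerned).
#' @export
validate_design <- function(design) {
  runs <- design$runs
  viol <- character(0)
  keys <- c("A1", "B1", "A2", "B2")
  if (!identical(sort(names(runs)), sort(keys))) {
    return(list(valid = FALSE,
                violations = "design must contain runs A1, B1, A2, B2"))
  }
  for (k in keys) {
    res <- tryCatch({ validate_schedule(runs[[k]]); NULL },
                    error = function(e) sprintf("run %s: %s", k, conditionMessage(e)))
    if (!is.null(res)) viol <- c(viol, res)
  }
  ref <- runs$A1
  for (k in c("B1", "A2", "B2")) {
    bad <- which(abs(runs[[k]]$onsets - ref$onsets) > 1e-9)
    if (length(bad)) {
      viol <- c(viol, sprintf("run %s: onset of event %d differs from A1",
                              k, bad[1]))
    }
    bad <- which(abs(runs[[k]]$durations - ref$durations) > 1e-9)
    if (length(bad)) {
      viol <- c(viol, sprintf("run %s: duration of event %d differs from A1",
                              k, bad[1]))
    }
  }
  dims <- names(ref$dim_levels)
  # same[[d]][k]: must run k agree with A1 event-by-event on dimension d?
  expect_same <- list(c(A1 = TRUE, B1 = FALSE, A2 = TRUE,  B2 = FALSE),
                      c(A1 = TRUE, B1 = TRUE,  A2 = FALSE, B2 = FALSE))
  for (di in 1:2) {
    d <- dims[di]
    for (k in keys) {
      agree <- runs[[k]]$labels[[d]] == ref$labels[[d]]
      if (expect_same[[di]][[k]]) {
        bad <- which(!agree)
        if (length(bad)) {
          viol <- c(viol, sprintf(
            "run %s: event %d label on dimension '%s' should match A1", k, bad[1], d))
        }
      } else {
        bad <- which(agree)
        if (length(bad)) {
          viol <- c(viol, sprintf(
            "run %s: event %d label on dimension '%s' should be twisted relative to A1",
            k, bad[1], d))
        }
      }
    }
  }
  list(valid = length(viol) == 0, violations = viol)
}
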