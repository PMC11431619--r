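#' Hotelling-Williams test for two dependent correlations
#'
#' Tests, per voxel, the null hypothesis that the seed's correlation with
#' the red reference equals its correlation with the blue reference
#' (`r_sr = r_sb`), using the Williams form of the statistic for two
#' correlations sharing a common variable:
#'
#' \deqn{t = (r_{sr} - r_{sb}) \sqrt{\frac{(n - 1)(1 + r_{rb})}
#'   {2 \frac{n - 1}{n - 3} |R| + \bar r^2 (1 - r_{rb})^3}}}
#'
#' with \eqn{|R| = 1 - r_{sr}^2 - r_{sb}^2 - r_{rb}^2 +
#' 2 r_{sr} r_{sb} r_{rb}} the determinant of the 3 x 3 correlation
#' matrix, \eqn{\bar r = (r_{sr} + r_{sb}) / 2}, and \eqn{n} the effective
#' sample size.  Degrees of freedom are `ess - 3` (non-integer ESS is
#' passed to the t distribution unrounded).  Positive t means the seed is
#' more consistent with the red reference (`r_sr > r_sb`).
#'
#' Voxels with `ess <= 4` or a non-positive denominator radicand (a
#' degenerate or non-positive-semi-definite triple, possible after
#' negative-correlation clipping) are flagged invalid; see
#' [handle_non_psd()] for the recovery policies.
#'
#' @param r_sr,r_sb,r_rb Correlation coefficients in \[-1, 1\]
#'   (vectorized).
#' @param ess Effective sample size(s), > 4 for a valid result.
#' @return List of vectors: `t`, `df`, `valid`, `det_R`.
#' @examples
#' hotelling_williams_t(-0.6, 0, 0, 100)  # t = -5.05, df = 97
#' @export
hotelling_williams_t <- function(r_sr, r_sb, r_rb, ess) {
  n <- pmax(length(r_sr), length(r_sb), length(r_rb), length(ess))
  r_sr <- rep_len(r_sr, n); r_sb <- rep_len(r_sb, n)
  r_rb <- rep_len(r_rb, n); ess <- rep_len(ess, n)
  if (any(abs(c(r_sr, r_sb, r_rb)) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  det_R <- 1 - r_sr^2 - r_sb^2 - r_rb^2 + 2 * r_sr * r_sb * r_rb
  rbar <- (r_sr + r_sb) / 2
  denom <- 2 * ((ess - 1) / (ess - 3)) * det_R + rbar^2 * (1 - r_rb)^3
  radicand <- (ess - 1) * (1 + r_rb) / denom
  ok <- is.finite(radicand) & denom > 0 & ess > 4 &
    is.finite(r_sr) & is.finite(r_sb) & is.finite(r_rb)
  t <- ifelse(ok, (r_sr - r_sb) * sqrt(pmax(radicand, 0)), NA_real_)
  list(t = t, df = ess - 3, valid = ok, det_R = det_R)
}

#' Fisher-Z comparison of two dependent correlations
#'
#' The classical z test for the difference of two Fisher-transformed
#' correlations sharing a common variable, accounting for their dependence
#' through the red-blue correlation.  Less sensitive than the Williams t
#' but defined for triples whose clipped correlation matrix is not
#' positive semi-definite.
#'
#' @inheritParams hotelling_williams_t
#' @return List of vectors `z`, `p` (two-sided) and `valid`.
#' @export
fisher_z_test <- function(r_sr, r_sb, r_rb, ess) {
  n <- pmax(length(r_sr), length(r_sb), length(r_rb), length(ess))
  r_sr <- rep_len(r_sr, n); r_sb <- rep_len(r_sb, n)
  r_rb <- rep_len(r_rb, n); ess <- rep_len(ess, n)
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z1 <- atanh(clamp(r_sr)); z2 <- atanh(clamp(r_sb))
  # covariance of the two correlations (shared seed variable)
  psi <- r_rb * (1 - r_sr^2 - r_sb^2) -
    0.5 * r_sr * r_sb * (1 - r_sr^2 - r_sb^2 - r_rb^2)
  s <- psi / ((1 - r_sr^2) * (1 - r_sb^2))
  s <- pmin(pmax(s, -1 + 1e-12), 1 - 1e-12)
  z <- (z1 - z2) * sqrt((ess - 3) / (2 - 2 * s))
  valid <- is.finite(z) & ess > 3
  list(z = z, p = 2 * pnorm(-abs(z)), valid = valid)
}

#' Resolve voxels whose clipped correlation matrix is inconsistent
#'
#' Clipping negative correlations to zero can leave a triple that no
#' positive-semi-definite 3 x 3 correlation matrix realizes, making the
#' Williams denominator non-positive.  Policies:
#' \describe{
#'   \item{invalidate}{(default) exclude the voxel, keeping a count.}
#'   \item{raw_correlations}{recompute the statistic from the unclipped
#'     triple.}
#'   \item{fisher_z}{fall back to [fisher_z_test()] on the clipped triple;
#'     the result carries `method = "fisher_z"` and the z value in `t`
#'     with `df = Inf`.}
#' }
#'
#' @param triple A `correlation_triple` (clipped and raw columns).
#' @param ess Effective sample sizes.
#' @param policy One of `"invalidate"`, `"raw_correlations"`,
#'   `"fisher_z"`.
#' @return List `t`, `df`, `p`, `valid`, `method` (per-voxel tag),
#'   `n_non_psd` (count of triples that needed the policy).
#' @export
handle_non_psd <- function(triple, ess,
                           policy = c("invalidate", "raw_correlations",
                                      "fisher_z")) {
  policy <- match.arg(policy)
  hw <- hotelling_williams_t(triple$r_sr, triple$r_sb, triple$r_rb, ess)
  ess <- rep_len(ess, length(hw$t))
  flagged <- !hw$valid & !triple$invalid & ess > 4
  out <- list(t = hw$t, df = hw$df,
              p = p_from_t(hw$t, hw$df)$p,
              valid = hw$valid & !triple$invalid,
              method = rep("williams", length(hw$t)),
              n_non_psd = sum(flagged))
  if (!any(flagged)) return(out)
  if (policy == "raw_correlations") {
    raw <- hotelling_williams_t(triple$raw_sr[flagged],
                                triple$raw_sb[flagged],
                                triple$raw_rb[flagged], ess[flagged])
    out$t[flagged] <- raw$t
    out$df[flagged] <- raw$df
    out$p[flagged] <- p_from_t(raw$t, raw$df)$p
    out$valid[flagged] <- raw$valid
    out$method[flagged] <- "williams_raw"
  } else if (policy == "fisher_z") {
    fz <- fisher_z_test(triple$r_sr[flagged], triple$r_sb[flagged],
                        triple$r_rb[flagged], ess[flagged])
    out$t[flagged] <- fz$z
    out$df[flagged] <- Inf
    out$p[flagged] <- fz$p
    out$valid[flagged] <- fz$valid
    out$method[flagged] <- "fisher_z"
  }
  out
}

#' p value from the t statistic
#'
#' Compares t against a t distribution with `df = ESS - 3` degrees of
#' freedom (non-integer df allowed).  Two-sided by default, since both
#' signs are interpreted (red- versus blue-selective); one-sided options
#' read the direction from the sign convention (positive = red).
#'
#' @param t Statistic values.
#' @param df Degrees of freedom (> 0 for validity).
#' @param sided `"two"` (default), `"greater"` or `"less"`.
#' @return List `p`, `valid`.
#' @export
p_from_t <- function(t, df, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  valid <- is.finite(t) & is.finite(df) & df > 0
  valid[is.na(valid)] <- FALSE
  p <- rep(NA_real_, length(t))
  p[valid] <- switch(sided,
    two = 2 * pt(-abs(t[valid]), df[valid]),
    greater = pt(t[valid], df[valid], lower.tail = FALSE),
    less = pt(t[valid], df[valid]))
  p <- pmin(p, 1)
  list(p = p, valid = valid)
}

#' Benjamini-Hochberg FDR across valid voxels
#'
#' Step-up FDR correction computed over the valid in-mask voxels only
#' (invalid voxels carry NA and do not enter the number of tests).
#'
#' @param p p values (NA for invalid voxels).
#' @param q_threshold Survival threshold (default 0.05).
#' @return List `q` (adjusted p values), `survives` (logical at
#'   `q_threshold`), `m` (number of tests).
#' @export
fdr_correct <- function(p, q_threshold = 0.05) {
  ok <- is.finite(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  list(q = q, survives = !is.na(q) & q < q_threshold, m = sum(ok))
}

#' Classify voxels into the four selectivity groups
#'
#' Assigns each voxel one of `non_responsive`, `non_selective`,
#' `red_selective` (dimension 1) or `blue_selective` (dimension 2):
#' voxels whose clipped correlations with both references fall below
#' `r_threshold` are non-responsive; responsive voxels with a significant
#' asymmetry are selective in the direction of the t sign; remaining
#' responsive voxels (the "diagonal" group, correlated with both
#' references) are non-selective.  The correlation threshold and the
#' significance rule are explicit configuration, not estimated quantities.
#'
#' @param triple A `correlation_triple`.
#' @param result Test results as returned by [handle_non_psd()] with `q`
#'   attached, or any list with `t`, `p`, `q`, `valid`.
#' @param r_threshold Responsiveness threshold on max(r_sr, r_sb)
#'   (default 0.1).
#' @param sig Which significance measure gates selectivity: `"q"`
#'   (FDR-corrected, default) or `"p"` (uncorrected).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of group labels (`NA` for invalid voxels).
#' @export
classify_voxels <- function(triple, result, r_threshold = 0.1,
                            sig = c("q", "p"), alpha = 0.05) {
  sig <- match.arg(sig)
  crit <- if (sig == "q") result$q else result$p
  responsive <- pmax(triple$r_sr, triple$r_sb) >= r_threshold
  selective <- !is.na(crit) & crit < alpha & responsive
  cls <- ifelse(!responsive, "non_responsive",
         ifelse(selective & result$t > 0, "red_selective",
         ifelse(selective & result$t < 0, "blue_selective",
                "non_selective")))
  cls[!result$valid] <- NA_character_
  cls
}

#' Group-level propagation of subject t maps
#'
#' Voxel-wise one-sample location test (ordinary least squares on the
#' subject-level t values, equivalently a one-sample t test) across
#' aligned subject maps, with the same FDR machinery applied to the group
#' p values.
#'
#' @param t_maps List of numeric arrays or vectors, one per subject, all
#'   of identical dimensions; NA entries are excluded voxel-wise.
#' @param q_threshold FDR survival threshold.
#' @return List `t`, `df`, `p`, `q`, `survives`, `n_subjects`.
#' @export
group_level <- function(t_maps, q_threshold = 0.05) {
  if (length(t_maps) < 2) {
    stop("group-level analysis needs at least 2 subject maps", call. = FALSE)
  }
  dims <- lapply(t_maps, function(m) dim(m) %||% length(m))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("subject maps are not aligned on the same grid", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(t_maps, as.numeric))
  n <- colSums(is.finite(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 2, sd, na.rm = TRUE)
  t <- mu / (sdv / sqrt(n))
  df <- n - 1
  p <- p_from_t(t, df)$p
  fdr <- fdr_correct(p, q_threshold)
  list(t = t, df = df, p = p, q = fdr$q, survives = fdr$survives,
       n_subjects = length(t_maps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
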