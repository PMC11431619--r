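---
title: "Model-free fMRI mapping with TWISTER designs and Temporal Consistency Asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free fMRI mapping with TWISTER designs and Temporal Consistency Asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twistca)
```

## The problem

Mass-univariate fMRI analysis usually assumes a linear generative model:
neural events convolved with a canonical hemodynamic response function
(HRF), plus Gaussian noise. That model is known to be violated in
interesting places — HRFs vary across regions, populations and cortical
depth, can be outright inverted, and event responses saturate rather than
add. A model-based analysis loses sensitivity exactly where the model
fails.

`twistca` implements a model-free alternative built from two pieces:

1. **TWISTER randomization** — an experimental design of four runs
   (A1, B1, A2, B2) with *identical event timing* whose event labels are
   "twisted" (inverted, or identity-free-permuted) along one or both of
   two experimental dimensions. A1 and A2 agree event-by-event on
   dimension 1 and disagree on dimension 2; A1 and B1 agree on
   dimension 2 and disagree on dimension 1; B2 disagrees with A1 on both.
2. **Temporal Consistency Asymmetry (TCA)** — a per-voxel statistic that
   compares the voxel's temporal correlation with a *red* reference
   (runs consistent with the seed on dimension 1) against its correlation
   with a *blue* reference (consistent on dimension 2). A voxel selective
   for dimension 1 reproduces its time course whenever dimension 1 is
   preserved, whatever the shape of its hemodynamic response, so the
   asymmetry of the two correlations is a model-free index of
   selectivity.

In the canonical eight-run layout the seed series is the concatenation
[A1, B2], the red reference [A2, B1] and the blue reference [B1, A2]:
each reference pairs every seed segment with a run that preserves exactly
one dimension.

## The statistic

For each voxel we compute the Pearson triple `r_sr` (seed–red), `r_sb`
(seed–blue), `r_rb` (red–blue) on per-run z-scored, concatenated series,
and test `r_sr = r_sb` with the Williams form of the Hotelling–Williams
test for two dependent correlations sharing a variable:

$$ t = (r_{sr} - r_{sb})\sqrt{\frac{(n-1)(1+r_{rb})}
   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{rb})^3}},
   \qquad df = n - 3, $$

where $|R|$ is the determinant of the 3×3 correlation matrix,
$\bar r = (r_{sr}+r_{sb})/2$, and $n$ is the voxel's *effective* sample
size (below). Positive $t$ means red-selective (dimension 1), negative
blue-selective. p values are two-sided by default because both signs are
interpreted; a one-sided option exists.

**Negative-correlation clipping.** Negative correlations between runs of
the same voxel have no interpretation as "consistency", so by default all
three coefficients are clipped at zero before testing
(`clip_negative = TRUE`; `clip_rb = FALSE` restricts clipping to the two
tested coefficients). The reference case: a voxel with
`r_sr = -0.6, r_sb = 0, r_rb = 0` at `ESS = 100` gives `t = -5.05`,
`df = 97` — nominally a strong blue preference, driven entirely by an
uninterpretable negative correlation; clipping removes it. Clipping can
only make the test more conservative.

**Clipping and inconsistent triples.** A clipped triple may not be
realizable by any positive-semi-definite correlation matrix (e.g.
`(0.9, 0.9, 0)`), making the Williams denominator non-positive. Three
policies are available (`non_psd_policy`): `invalidate` (default —
exclude the voxel and count it), `raw_correlations` (retest with the
unclipped triple), and `fisher_z` (a Steiger-type dependent-correlation
z comparison, tagged in the output; less sensitive, but defined for such
triples).

## Effective sample size

BOLD noise is temporally autocorrelated, so the N acquired volumes carry
fewer than N independent observations. We use the autocorrelation-time
correction

$$ ESS = \frac{N}{1 + 2\sum_{k\ge 1} ACF_k} $$

estimated per voxel on each of the three role series, averaged, and then
robustly smoothed across neighbouring voxels (a median filter over the
in-mask 26-connected neighbourhood; radius configurable,
`smoothing_radius = 0` disables it). The infinite sum is truncated by the
*initial positive sequence* rule — accumulate sample ACF values until the
first non-positive one, with a hard cap at lag N/4 — which is standard
practice for autocorrelation-time estimation and prevents noise-dominated
tails from collapsing the estimate. ESS is capped at N; voxels with
ESS ≤ 4 are invalid because the test needs df = ESS − 3 > 0. The possibly
non-integer ESS is passed to the t distribution unrounded.

Computing ESS per concatenated role series (rather than per raw run) and
averaging the three estimates mirrors how the correlations themselves are
computed; with per-run z-scoring the two choices agree closely.

**A calibration note.** This ESS is the effective sample size for a
*mean*. The sampling variance of a correlation between two series with
autocorrelation $\rho_k$ scales with $1 + 2\sum_k \rho_k^2$ (squared
terms), which is smaller; using the mean-ESS therefore over-corrects, and
the test is conservative under autocorrelated noise. Simulated-null runs
of the full pipeline at this package's reference conditions (2048 in-mask
voxels, AR(1) φ = 0.3, 120-event 270-s runs at TR = 2 s), as exercised in
the test suite, reject at the 5% level at a rate on the order of 1–2%
with raw correlations and essentially 0% with default clipping. Type-I
error is protected — at a cost in power, consistent with the method's
stated conservatism.

## The synthetic-data generator

Because the method's selling point is robustness to response shapes that
break linear models, the simulator is a first-class module rather than a
fixture. A voxel's event drive is
`w_onset + code(dim1) * w_dim1 + code(dim2) * w_dim2` at each event frame,
with binary levels coded ±1, so "selective" means *differential* response
(`w_dim*`) and mere responsiveness is carried by `w_onset` — this keeps
"responsive but non-selective" and "selective" populations distinct. The
drive is convolved with one of four kernels:

* `canonical` — double-gamma (peak 6 s, undershoot 16 s, ratio 1/6 by
  default, unit peak);
* `latency_shifted` — canonical delayed by `shift` seconds;
* `inverted` — negated canonical;
* `saturating` — canonical followed by `s·tanh(x/s)` *after* convolution,
  so close events produce sub-additive responses.

Noise is stationary AR(1) (marginal sd and φ configurable, default
φ = 0.3 at TR = 2 s) plus an optional slow sinusoidal drift, drawn
independently per run from seed-derived streams; everything is
bit-reproducible from one seed. Default study conditions follow the
reference design: 120 events of 500 ms per 270-s run, ≥ 500 ms onset
separation, TR = 2 s (135 volumes/run); grids are kept small
(hundreds to a few thousand voxels) so the full pipeline runs in seconds.

What the simulator does *not* emulate: spatial noise correlations,
physiological (cardiac/respiratory) noise, motion, susceptibility
artifacts, or between-subject variability beyond seeds. Passing tests on
simulated data show that the statistical machinery behaves as designed
under known ground truth and under HRF-assumption violations; they do not
certify performance on real acquisitions, where preprocessing quality and
structured noise dominate.

## Design choices that were genuinely open

* **Onset sampling** — "randomly dispersing" events is implemented by
  drawing n uniform points on the interval shrunk by the total
  minimum-gap budget, sorting, and adding back cumulative gaps: exactly
  uniform over feasible schedules, O(n log n). Onsets are quantized to
  1 ms so events files serialize bit-exactly.
* **Twisting** — binary dimensions default to event-wise inversion
  (maximal inconsistency); multi-level dimensions use a uniformly drawn
  fixed-point-free level permutation (rejection-sampled derangement).
* **Sub-run splitting** — `build_design(split = 2 or 3)` records equal
  split boundaries and a seeded presentation order for mitigating
  order effects; label content is untouched, and balance is enforced at
  the run level only.
* **Classification thresholds** — the four-group classification
  (non-responsive / non-selective / red / blue) uses an explicit
  responsiveness threshold (`r_threshold = 0.1` on max(r_sr, r_sb)) and
  the FDR-corrected significance of t; these boundaries are configuration,
  not estimated quantities.
* **Degenerate inputs** — zero-variance voxels are flagged invalid at
  standardization (never silently zeroed); invalid voxels are excluded
  from the number of FDR tests and reported in the provenance log by
  reason.

## Problem sizes used in the shipped tests

Unit and property tests use 24-event/60-s designs on 32–72-voxel grids;
the calibration study uses 2048 voxels at the full 120-event design; the
recovery study uses 400 voxels with all four ground-truth classes under
each kernel family; ESS closed-form checks use series of length 3000 over
50 seeds. These sizes give Monte-Carlo error comfortably inside the
asserted tolerances while keeping a full test run in minutes.

## Limitations

The package consumes *preprocessed* NIfTI runs: motion correction,
temporal filtering and registration are upstream concerns. Group-level
propagation is a simple voxel-wise one-sample test on subject t maps.
Only voxel-wise thresholding is provided (no cluster-extent inference).
The test is conservative under temporal autocorrelation (see the
calibration note), and clipping adds further conservatism when negative
correlations are common — the `raw_correlations` and `fisher_z` policies
are the documented escape hatches.
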