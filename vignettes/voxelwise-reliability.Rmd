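---
title: "Voxel-wise reliability of repeated statistical maps: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise reliability of repeated statistical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relimap)
```

# The problem

When a statistical image — most commonly a subject-level task-fMRI contrast
map — is measured twice per subject (two runs, or two sessions), the question
"is this measure reliable?" becomes a voxel-wise variance decomposition
problem. At each voxel we observe a complete `n × k` table of values
(`n` subjects, `k` occasions) and ask how much of its variance is stable
between-subject signal versus occasion-to-occasion noise. `relimap`
implements that decomposition, the intraclass correlation coefficients built
on it, the binary/continuous similarity of group-level maps, bootstrap
sample-size stability curves, and specification-curve aggregation across
analytic pipelines, together with a synthetic generator that makes all of it
testable against known ground truth.

# The variance model and the ICC family

The two-way ANOVA of one voxel's table yields `MSBS` (between subjects),
`MSBM` (between measures — the occasion main effect) and `MSError`
(subject × occasion residual). The estimators are the single-measure
Shrout–Fleiss forms:

* **ICC(3,1)** (consistency; occasions fixed):
  `(MSBS − MSError) / (MSBS + (k−1) MSError)`. For `k = 2` this equals
  `σ²_r / (σ²_r + σ²_v)` with `σ²_r = (MSBS − MSError)/k` and
  `σ²_v = MSError`. A constant additive shift of any occasion leaves it
  unchanged.
* **ICC(2,1)** (agreement; occasions random): the denominator additionally
  carries `k (MSBM − MSError) / n`, so systematic occasion bias is penalised.
  The between-measure variance `(MSBM − MSError)/n` is reported as a third
  component map.
* **ICC(1)** (one-way): occasion variation is pooled into the within-subject
  mean square `MSW = (SS_measure + SS_error) / (n(k−1))`.

Assumptions are the usual ANOVA ones — additive Gaussian effects, homogeneous
variance across subjects, a complete design (no missing cells). The package
is deliberately strict about completeness: missing cells raise an error
rather than being imputed.

Three consequences of the estimator algebra are worth making explicit because
the test suite asserts them:

1. negative estimates are legitimate (sampling noise around a small true ICC)
   and are *not* truncated to zero, so distributions of map medians can
   extend slightly below 0;
2. the additive-bias penalty on ICC(2,1) has a determinate direction only
   when the estimate is positive — for a negative ICC, occasion bias shrinks
   the magnitude toward zero;
3. ICC(3,1) is invariant to a common affine rescaling `y → a·y + b` (`a > 0`)
   of all volumes.

# Confidence bounds

Bounds are F-quantile based (no bootstrap), two-sided at `1 − α` with
`α = 0.05` by default:

* `icc_3`: `F = MSBS/MSError` on `(n−1, (n−1)(k−1))` df;
  `FL = F / qF(1−α/2)`, `FU = F · qF(1−α/2)` with the df swapped for the
  upper quantile; each transformed by `(F* − 1)/(F* + k − 1)`.
* `icc_1`: analogous with `MSW` on `n(k−1)` df.
* `icc_2`: the McGraw–Wong interval, with the denominator degrees of freedom
  `v` from the Satterthwaite approximation evaluated at the point estimate.
  The published sources do not fix every convention for this interval; we
  follow the form used in the established Python implementations of the same
  estimator family, and the test suite pins the worked-example interval to
  that reference.

Degenerate cases are deliberate decisions, not accidents of floating point:

* **Zero total variance** at a voxel (all `n × k` cells equal): there is no
  reliability information, so the estimate and bounds are `NA` and the
  result is flagged `degenerate`. Maps propagate this as a quiet missing
  value; medians and similarities skip it. Returning 0 or 1 would bias map
  summaries in opposite directions, and neither is defensible.
* **Zero residual with nonzero subject variance** (perfect consistency): the
  estimate is 1 and the `icc_3`/`icc_1` interval is `(1, 1)` by convention,
  flagged `perfect`. For `icc_2` the interval collapses to the point
  estimate (its estimate can be below 1 when occasion bias is present, and
  the Satterthwaite machinery is undefined at `MSError = 0`).
* Numerical tolerances: degeneracy is declared at total SS below
  `1e−18 × max(1, mean squared signal) × nk`; perfection at residual MS
  below `1e−12 ×` the subject MS. Sums of squares use centred deviations,
  and the voxel-wise path clips tiny negative residual SS (from the
  subtraction identity) at zero.

# Map similarity

Binary similarity binarizes at a strict `value > threshold` on the positive
tail only — group activation maps are conventionally thresholded one-sidedly
(z > 3.1, p < .001, or Cohen's d > 0.40 after converting t maps with
`d = t/√N`), and binarizing the negative tail is a different scientific
question. A threshold of exactly 0 is the "no thresholding" convention:
every in-mask voxel becomes 1 and any two maps compare as identical
(similarity 1). Spearman similarity ranks the unthresholded in-mask values
with average ranks for ties. An empty union (Jaccard/Dice) or zero rank
variance (Spearman) produces an `NA` coefficient carrying its reason rather
than an arbitrary number; `pairwise_similarity` keeps such rows.

Volumes and maps are matched by list/manifest order, never by filename
parsing: the manifest (an ordered `occasion`/`path` TSV) is the single
auditable statement of subject correspondence.

# Bootstrap stability curves

`subsample_stability` draws, for each candidate sample size `n` and
iteration, `n` subjects *with replacement*, keeping the same subjects across
occasions (paired resampling is the only scheme that preserves the
within-subject structure the ICC measures). The defaults — sizes 25 to 525
in steps of 50, 100 iterations per size — match the standard design for
locating the sample size at which the median ICC stabilises. Sampling with
replacement means a subject can appear twice as two identical rows, which
slightly deflates between-subject variance in a resample; this is inherent
to the resampling definition and documented rather than corrected.

The per-`n` summary is the mean and the empirical 2.5/97.5 percentile band
across iterations (the "95% interval" of a stability plot; no distributional
form is assumed). Randomness is organised as one master seed spawning an
arithmetic substream per `(n, iteration)` cell, so extending the size grid
reproduces all earlier draws bit-exactly.

# Specification curves

`enumerate_pipelines` freezes the analytic-decision vocabulary: five
smoothing kernels (FWHM 3.6–8.4 mm), motion-correction strategies `opt1–opt4`
(the two additional mean-FD-exclusion variants `opt5`/`opt6` are available
via `full_motion_grid = TRUE`), three task parameterizations
(`AntMod`, `CueMod`, `FixMod`) and four contrasts (`LgainBase`, `LgainNeut`,
`SgainBase`, `SgainNeut`) — 240 pipelines by default, 360 on the full grid.

`build_specification_curve` aggregates one statistic per pipeline across
samples. With typically only three samples, the across-sample 95% interval
is taken as `mean ± t(0.975, s−1) · SE`; a single sample degenerates to the
point estimate. Pipelines are classed `null_gray` when the interval spans
the null (0 for ICC curves), otherwise `positive_blue`/`negative_red` by the
side of the null. Ordering is ascending in the point estimate with
lexicographic tie-breaks on the pipeline label, so the curve is identical
run to run. The decision panel is emitted as a pipeline × option-level 0/1
matrix with exactly one marked level per category.

`summarize_multiverse` computes the records feeding the curve: masked
medians of the estimate/BS/WS maps taken separately over a suprathreshold
(task-positive) and a disjoint subthreshold mask, because reliability in and
outside task-engaged tissue differ systematically and averaging them hides
both.

# The synthetic generator: what it does and does not emulate

`simulate_dataset` draws
`y_ijv = μ_v + b_iv + s_j + e_ijv`, with voxel-wise Gaussian subject effects
`b_iv ~ N(0, σ²_r(v))`, noise `e_ijv ~ N(0, σ²_v(v))`, and a fixed additive
occasion bias `s_j`. The true consistency ICC is then exactly
`σ²_r/(σ²_r + σ²_v)` per voxel, the bias affects only agreement-type
estimators, and the generator returns those truths alongside the volumes.
The Gaussian form matches the implicit assumptions of the ANOVA estimators;
defaults (60 subjects — a small two-session study; `k = 2`; an 8×8×8 grid;
`σ²_r = σ²_v = 1`, true ICC 0.5; no bias; a 25% suprathreshold mask) are
fixed once as a realistic small-study configuration.

Voxels are independent by default. An optional Gaussian smoothing
(`smooth_fwhm`, in voxels) induces spatial autocorrelation in the subject
and noise fields; each separable axis pass is a `d × d` linear operator and
fields are divided by the per-voxel root-sum-of-squared weights, so marginal
variances are preserved exactly even at edges. What the generator does *not*
emulate: BOLD timeseries and HRF structure, physiological/motion artefacts,
spatially varying smoothness, non-Gaussian tails, or dropout. Passing
parameter-recovery tests therefore validates the estimator chain, not the
behaviour of any real acquisition.

# Problem sizes in the test suite

The tests run the full chain at deliberately small scale: oracle-equivalence
sweeps on 4×4×4 grids with 8 subjects; parameter recovery at `n = 150`,
`k = 2` on a 6×6×6 grid (216 voxels) over 50 seeds and true ICCs of 0.2,
0.5 and 0.8 (recovery bias below 0.02 on the ICC and 10% relative on the
variance components); stability curves on ≤150 subjects with 15–25
iterations. These sizes were chosen so the whole suite exercises every code
path in seconds while keeping Monte-Carlo error well inside the asserted
tolerances; the estimators themselves are vectorised and run comfortably at
real-study scale (hundreds of subjects, ~10⁵ in-mask voxels).

# Known limitations

* Single-measure ICCs only; average-measure forms ICC(·,k) are out of scope.
* No surface (GIFTI/CIFTI) support; volumes only, matched on a common grid.
* No cluster-extent or permutation-based thresholding; binarization is a
  plain voxel-wise cut.
* The hierarchical regression of median estimates on analytic options (and
  marginal R² attribution) is intentionally not reimplemented — those are
  off-the-shelf mixed-model fits, downstream of the records this package
  produces.
* `MSBM < MSError` yields a negative between-measure variance component for
  `icc_2`; the raw value is propagated (flagging it would hide a usefully
  diagnostic quantity).

```{r example}
# the whole chain in miniature
tb <- simulate_dataset(simulation_spec(n_subjects = 40, grid_dims = c(5, 5, 5),
                                       sigma2_between = 1, sigma2_within = 1,
                                       seed = 3))
maps <- voxelwise_icc(tb$volumes, tb$mask, "icc_3")
c(median_icc = masked_median(maps$estimate, tb$mask),
  median_bs = masked_median(maps$between_subject_var, tb$mask),
  median_ws = masked_median(maps$within_subject_var, tb$mask))
```
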