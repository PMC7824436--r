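---
title: "Methods: volumetric segmentation, reliability, and normative modeling in brainvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric segmentation, reliability, and normative modeling in brainvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

brainvol implements a complete regional brain volumetry pipeline: T1-weighted
volumes are resampled, intensity-standardized and padded; a 3-D nested U-Net
(UNet++) segments them patch-wise; predictions are stitched, cleaned by
connected-component filtering and mapped back to the native grid; regional
volumes feed two-way intraclass-correlation (ICC) reliability analyses,
normative age tables, and covariate-adjusted group-difference models. A
synthetic phantom and cohort generator reproduces the statistical structure
each stage assumes, so everything here runs and is tested without imaging
data.

This vignette records the model assumptions, the tunable parameters, and the
design decisions that were genuinely open, in the order the pipeline runs.

## Preprocessing

`resample_isotropic()` maps voxel centers through physical space
(target spacing default 1 mm), with trilinear interpolation for intensities
and nearest-neighbor for label maps; label maps may never be interpolated
linearly. `zero_pad()` pads each axis symmetrically to the next multiple of
16 (training) or 24 (inference), the extra voxel going to the high side, and
returns a crop record that inverts the pad exactly. The pad-to-multiple
rule makes every axis divisible through the encoder's pooling levels; a
conformed 181 x 217 x 181 volume becomes 192 x 224 x 192 (training) or
192 x 240 x 192 (inference).

Intensity standardization is landmark-based (Nyúl-style): per volume, the
percentiles {1, 10, 20, ..., 90, 99} of the foreground intensities are
extracted; the cohort reference is the per-percentile mean
(`fit_reference_landmarks()`); `histogram_match()` then applies the
piecewise-linear map sending a volume's own landmarks onto the reference,
with linear extrapolation beyond the outer landmarks. The map is monotone,
so intensity order is preserved. **Foreground rule.** Foreground is
"intensity above the volume mean". On MRI-like volumes the intensity
histogram is bimodal — a dark background mode and a bright tissue mode
separated by a sparsely populated gap — and the volume mean falls inside
that gap. Two consequences follow: the selected voxel set is identical
before and after the monotone map (the matching is idempotent), and all
landmarks lie inside the tissue range, away from the background/tissue
jump. The jump matters: a threshold low enough to admit background (a
median cut, say) puts the steep background-to-tissue transition *inside*
the landmark set, and because the transition sits at a different percentile
in every subject, the piecewise-linear map then stretches background noise
across the gap and degrades tissue contrast — measurably harming the
downstream segmentation. Landmarks are type-1 (order-statistic) quantiles,
so a monotone map carries each landmark exactly onto the mapped order
statistic and idempotence is exact rather than approximate: re-matching a
matched volume moves its landmarks by less than 1e-6 of the intensity
range. The idempotence property is stated for this bimodal intensity
class; for a unimodal continuous intensity distribution no adaptive
threshold selects a stable foreground and the property is only
approximate. Constant volumes are returned unchanged with a warning.

## The segmentation network

`build_model()` constructs the nested topology: nodes `X(i, j)` for
`i + j <= n_levels - 1`, channels doubling with depth
(`base_channels * 2^i`). `X(i, 0)` is the encoder column (2x2x2 max-pool
between levels); every decoder node `X(i, j)` receives the 2x-upsampled
`X(i+1, j-1)` (trilinear resize followed by a convolution unit)
concatenated with *all* same-level predecessors `X(i, 0..j-1)`, each
passing through its own convolutional skip unit — the dense, convolutional
skip path that distinguishes UNet++ from a plain U-Net. A convolution unit
is a 3x3x3 convolution (mirror/reflect-101 padded, so patch borders see
plausible context rather than an artificial dark rim) followed by ReLU; a
conv block is two units by default (`block_units = 2`, the reference
design) or one (`block_units = 1`), which halves the compute and the
minimum receptive field — the configuration recommended, and used by the
test suite, for short training schedules, where the larger receptive field
of the two-unit block leaves a systematic fraction-of-a-voxel boundary
erosion on small structures that the step budget cannot train away. With
deep supervision on (default), every top-row decoder node `X(0, j)` carries
a 1x1x1 softmax head, the loss is the unweighted mean of the per-head
voxel-wise cross-entropies, and inference may use any head ("pruned"
inference); the deepest head is the default because it sees the full nested
computation. Training is Adam at learning rate 1e-4, batch size 1 (one
uniformly sampled patch per iteration), with the loss trace recorded per
head. Adam's second-moment decay defaults to `beta2 = 0.99` rather than
the long-schedule convention 0.999: the variance estimate then adapts
within tens of iterations, which measurably improves what a 300-step
schedule can learn; both moments are configurable in `train_config()`.

Several choices here were genuinely open and matter at small step budgets:

* **Zero-initialized head weights, log-prior head biases.** The 1x1x1 head
  weights start at zero, so the initial prediction carries no random
  signal and every argmax decision after training reflects learned
  structure. With a fixed learning rate of 1e-4, per-parameter movement
  after *T* Adam steps is bounded by roughly `1e-4 * T`; had the heads
  started at He scale, that movement could not dominate the
  initialization for small *T*. The same bound means the biases cannot
  learn the class frequencies within a short schedule, so `train_model()`
  initializes them to the log class frequencies of the training labels
  (`prior_bias_init = TRUE`), the standard prior-initialization trick:
  the step budget is then spent on discrimination, not on re-deriving
  priors through the weights.
* **He-scaled orthogonal convolution initialization** (default
  `init = "he"`, orthonormal columns from a QR decomposition scaled to
  the He norm). With as few as eight channels, independent Gaussian
  kernels can come out nearly collinear by chance, and the quality of the
  random feature basis then varies visibly across seeds; orthogonal
  columns remove that failure mode. An
  identity-preserving Dirac/He hybrid (`init = "he_dirac"`, delta kernels
  on the leading channels) is also implemented — identity propagation is
  attractive for deep schedules — but it is *not* the default for a
  reason worth recording: when a strong common intensity direction is
  added to every channel, a three-class problem whose classes are ordered
  by intensity (background, gray matter, white matter) requires the
  softmax head to carve out the *middle* class with bias offsets
  proportional to the intensity scale, and under a bounded per-parameter
  step budget those offsets cannot materialize; the minority middle class
  is then never predicted. Sign-diverse random He features avoid imposing
  that ordering and let the heads separate all three classes within the
  budget.
* **Mirror-padded convolutions.** 'Same' convolutions must invent context
  at patch borders. Zero padding — the common default — surrounds every
  training patch and sliding window with an artificial dark rim whose
  corrupted features systematically under-segment structures that fall
  near a window border; reflect-101 padding supplies plausible mirrored
  context instead. (Volume-level padding to encoder-compatible grid
  multiples remains zero padding, as the preprocessing contract states.)
* **No normalization inside conv units by default.** With batch size 1,
  batch normalization degenerates to instance normalization, and
  instance-normalized features cap the attainable logit magnitude at
  roughly `(channels + 1) * lr * T` — about ±0.3 after 300 steps at 1e-4 —
  which is not enough for a cross-entropy head to commit to a minority
  class. Instance normalization is implemented
  (`normalization = "instance"`) and is the sensible choice for long
  schedules; the short-schedule default is plain conv + ReLU.

All size parameters (96³ patches, label count, iteration count) are
configuration, not constants; the test suite trains a 2-level, 8-channel
model on 32³ patches.

## Whole-volume inference and postprocessing

`sliding_window_segment()` tiles the padded volume with overlapping windows
(default 96³, overlap 16; the final window per axis snaps to the volume
boundary so coverage is complete), blends the per-voxel softmax
probabilities over all covering windows, and takes the argmax with ties
broken toward the lowest label id — choices fixed for determinism; window
visit order cannot affect the result because the blend is commutative.
Blending is a center-weighted (Gaussian, sigma = size/4) average by
default, with uniform averaging available: predictions near a window
border are computed with truncated spatial context (the convolutions see
zero padding there), and weighting windows by voxel-to-center proximity
measurably removes the under-segmentation of small structures that happen
to fall near window borders. `connected_component_filter()` keeps, per label, only the
largest connected component (26-connectivity default, 6 available);
equal-sized components are broken deterministically by keeping the one
containing the smallest linear voxel index; removed voxels become
background rather than being relabeled to a neighbor. Finally
`to_original_space()` inverts the pad via the crop record and
nearest-neighbor-resamples onto the native grid, so reported volumes are
computed on the acquisition grid (`compute_roi_volumes()`:
voxel count x voxel volume / 1000, in mL), never on a resampled one.

## Reliability statistics

Repeated measurements of the same subjects form an n x k matrix (subjects x
raters, where a "rater" is a visit in test-retest designs or a site in
traveling-subject designs). From the two-way ANOVA mean squares (rows
MS_R, columns MS_C, residual MS_E):

* consistency (two-way mixed, single rater):
  `ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)` — systematic rater
  offsets are absorbed by the column effect;
* absolute agreement (two-way random, single rater):
  `ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))` —
  rater variance is penalized, so agreement <= consistency whenever
  MS_C >= MS_E and MS_R >= MS_E.

Single-rater (not average-measure) forms are used throughout because the
scientific claim concerns a single scan's measurement. Estimates at or
above 0.75 are flagged reliable, the conventional cutoff for good
reliability; negative estimates are reported as computed and flagged
unreliable, not clipped. A zero-variance matrix has no defined ICC and
raises an error. Confidence intervals and F-tests are out of scope.
`reliability_report()` pivots a long volume table into one complete matrix
per (region, hemisphere) and errors with the list of missing cells on
incomplete designs.

## Normative tables and adjusted group differences

`build_normative_table()` bins cognitively normal subjects by decade
(10-19 ... 90-99) and reports n, mean, SD and the 5/25/50/75/95th
percentiles per (region, hemisphere, bin); single-subject bins are flagged,
empty bins omitted.

`adjusted_group_difference()` estimates the volume difference of a patient
group relative to the normal reference by ordinary least squares — the
Gaussian-identity case of the generalized linear model — of the region
volume on a group indicator plus age at scan, sex, site (dummy-coded,
first observed site as reference) and intracranial volume (ICV). The
reported quantity is the group coefficient in mL with its standard error
and a two-sided p from the t distribution at residual degrees of freedom.
MCI and dementia are fitted in separate models against the same normal
reference, matching the way such contrasts are conventionally tabulated.
Education is summarized descriptively but is not a covariate. No
multiple-testing correction is applied to the primary p-values; a
Bonferroni column is appended as clearly supplementary output.
Rank-deficient designs (e.g. a site containing only one group) raise an
error naming the collinear terms rather than silently dropping them.
`age_stratified_analysis()` re-runs the same model inside closed integer
age bins (default 71-80 and 81-100, where patient groups have support),
keeping age as a covariate within the bin.

## The synthetic cohort generator

`generate_cohort()` is the package's study-condition generator, not a
convenience fixture; its defaults are the conditions under which the
pipeline is validated, and every cohort ships with a truth ledger of its
injected parameters so recovery tests never read expectations from
anywhere else.

Demographics: group sizes default to 992 normal / 524 MCI / 163 dementia;
normal ages are uniform on 18-96 while patient ages are truncated normal
(means 75.2 and 78.9, SDs 8.2 and 8.4) — patient cohorts of this kind are
old, and a uniform patient age distribution would make age adjustment and
age-stratified analysis vacuous. ICV is drawn per group
(1519.3 ± 136.5 mL for normals, slightly smaller means for patients), sex
is Bernoulli per group (64-71% female), and normal subjects are spread
over five sites with weights matching a realistic multi-source mix, while
patients are recruited at the first site only.

Volume model, per region and hemisphere:

```
volume = baseline * f(age) + baseline * (ICV/1519.3 - 1) + effect(group) + N(0, sd)
```

* **Age trajectories.** Gray-matter regions follow a *tent*: volume rises
  linearly to a peak at 35 years (about 4% over ages 18-35) and declines
  linearly thereafter (about 15% by age 90); the frontal lobe declines
  monotonically from the start of the age range; the lateral ventricle
  grows linearly (0.30 mL/year). The tent was chosen over a smooth
  quadratic deliberately: the adjusted-difference model includes age
  *linearly*, and any curvature shared across the adult range loads onto
  the group coefficient because patients and normals have different age
  distributions. Design arithmetic at the default group sizes puts that
  confounding bias at ~21% of the injected effect for a large region under
  a quadratic with a 15% lifetime decline, versus <= ~5% for the tent,
  whose only nonlinearity (the kink at 35) lies where patients have
  essentially no mass. A rise-then-linear-decline shape is equally
  consistent with the qualitative aging literature, and it keeps the
  estimator the pipeline actually uses well-specified — which is what a
  validation cohort is for.
* **ICV scaling** is additive (`baseline * (ICV/ref - 1)`) rather than
  multiplying the whole age trajectory, so the model's linear ICV covariate
  is exactly correct.
* **Group effects** are additive in mL, applied after the age trend:
  atrophy (negative) for tissue regions, enlargement (positive) for
  ventricles, at magnitudes typical of adjusted clinical volumetry
  (`default_group_effects()`; e.g. left hippocampus MCI -0.37 mL, left
  lateral ventricle dementia +9.63 mL). Setting them to zero yields a
  calibrated null for type-I-error checks.
* **Residual SDs** are calibrated so that the model's standard errors come
  out at realistic magnitudes for the default n (e.g. hippocampus 0.4 mL,
  frontal 5.6 mL, ventricle 6 mL). Draws below 0.1 mL are truncated there
  and counted in a warning; at the defaults this affects a handful of
  draws per ten thousand.

`generate_testretest()` re-measures the same true volumes k times with a
per-visit coefficient of variation (default 1%, between-subject 10%;
expected consistency ICC ~ 0.10² / (0.10² + 0.01²) ≈ 0.99).
`generate_multisite()` implements the traveling-subject design: identical
anatomy at every site, site differences being intensity-only by default,
with an opt-in multiplicative volume bias for stress tests (a 2% bias with
1% noise pushes agreement visibly below consistency).

`generate_phantom()` builds image/label pairs from analytically defined
ellipsoids (an enclosing intracranial ellipsoid that inner regions carve
into), so true volumes are known in closed form ((4/3)πabc, within ~2% of
the voxelized count at 1 mm for semi-axes above ~7-8 mm); intensities are
per-tissue Gaussians with optional per-site gain/gamma/bias-field
transforms. Same seed, same bits.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: cortical folding and partial-volume effects
(phantom boundaries are crisp; real boundary voxels mix tissues), scanner
physics and artifacts, nonlinear or heteroscedastic age effects beyond the
tent, site effects on anatomy, longitudinal change within subject, and
label noise in training references. Results here validate the
*implementation* of each stage under its stated statistical model, not
clinical performance.

## Numerical choices and degenerate inputs

* Argmax ties: lowest label id. Component-size ties: smallest linear index.
  Both fixed so reruns are bit-identical.
* Sliding-window boundary: last window snapped inside the volume; every
  voxel covered at least once for any stride in (0, size].
* Histogram matching of a constant volume: identity with a warning.
  Duplicate source landmarks are collapsed before interpolation.
* Both-empty masks in `dice()`: defined as 1 with a warning.
* ICC on a zero-variance matrix, empty landmark input, labels missing from
  a scheme, non-3-D NIfTI inputs, rank-deficient GLM designs: explicit
  errors, never silent repair.
* mL = cm³ = 1000 mm³ everywhere; volumes always from voxel counts times
  spacing products, never from resampled grids.
* With a fixed seed and a fixed BLAS thread count, training runs are
  reproducible; the loss trace is part of the model object.

## Problem sizes used by the test suite

The suite exercises the full pipeline at desk scale, chosen as the smallest
sizes at which each property is meaningfully tested: segmentation
end-to-end on twenty 48³ two-structure phantoms (intracranial ellipsoid
plus a 3.55 mL hippocampus-sized inner ellipsoid) with a 2-level,
8-channel, single-unit-block network on 32³ patches for 300 iterations
(held-out Dice and closed-form volume recovery on five further phantoms); ICC estimators against a brute-force ANOVA oracle on 200
random matrices; GLM recovery on cohorts at the full default group sizes
over 50 replicates; type-I error on 100 null cohorts of 600 subjects. The
acceptance script regenerates the reliability and GLM quantities from
scratch at the same sizes.

## Known limitations

* The network trains on one CPU at small scale; there is no GPU path, and
  full-scale (10⁵-iteration, 100-label, 96³-patch) training, while
  configurable, is not a realistic use of this implementation.
* Histogram matching assumes reasonably similar acquisition contrast;
  it cannot harmonize fundamentally different sequences.
* The GLM stage models volumes as Gaussian with homoscedastic errors;
  percentile-curve methods (e.g. GAMLSS) and longitudinal models are out
  of scope, as is batch harmonization such as ComBat.
* ICC point estimates are reported without confidence intervals.
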