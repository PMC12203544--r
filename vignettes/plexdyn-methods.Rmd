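---
title: "Methods: choroid plexus segmentation, ratio mapping and long-term trajectory estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choroid plexus segmentation, ratio mapping and long-term trajectory estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexdyn)
```

plexdyn implements, end to end, the computational machinery of a
longitudinal choroid plexus (ChP) study in relapsing-remitting multiple
sclerosis: segmentation of the plexus inside the lateral ventricles from
T1-weighted images, calibrated T1w/T2w intensity-ratio mapping as a proxy
for tissue microstructure, estimation of long-term biomarker trajectories
over disease duration from short staggered follow-ups, and a mixed-model
association layer. Because patient images and records cannot be
redistributed, the package ships generators for synthetic phantom images
and synthetic cohorts whose generating parameters are set to the published
cohort's characteristics; every stage can therefore be verified against
known ground truth. This vignette explains each model, its assumptions,
the tunable parameters, and the design decisions taken where the published
description leaves the design open.

## Choroid plexus segmentation

The plexus is the only bright structure inside the CSF-dark lateral
ventricles on T1w images. `segment_chp()` exploits that contrast in two
stages:

1. a two-component Gaussian mixture (`fit_gmm()`) over the in-ventricle
   intensities separates CSF from brighter voxels; the higher-mean
   component is retained;
2. the retained voxels are smoothed with the SUSAN structure-preserving
   filter (`susan_smooth()`, default sigma 1 mm), and a three-component
   mixture over the smoothed intensities keeps only the highest-mean
   component as the final plexus mask. The two discarded components absorb
   partial-volume voxels at the CSF boundary and the ventricular wall.

The mixtures are fitted by maximum-likelihood EM with k-means
initialization and five seeded restarts. A variational treatment with a
weight-concentration prior would not change the decision rule the pipeline
depends on - membership of the highest-mean component - while EM keeps
that rule deterministic and directly checkable against phantom ground
truth, so EM is the implementation. Component variances are floored at
`1e-4 * var(values)`: the floor must be loose enough that a spectrally
pure intensity spike (a noise-free plexus) still attracts voxels whose
smoothed intensity sits a hair off the spike.

SUSAN weights each neighbour within 3 sigma by spatial distance and
intensity similarity,
$w(x) = \exp(-\|x-x_0\|^2/2\sigma^2)\exp(-((I(x)-I(x_0))/t)^2)$,
so averaging never crosses tissue boundaries. The brightness threshold $t$
is not published; it defaults to 10% of the robust (2nd-98th percentile)
in-ventricle intensity range, mirroring common practice in the reference
implementation. Expressing it as a fraction makes the whole segmentation
invariant to affine intensity rescaling of the input, which the test suite
asserts exactly.

Segmented volumes are reported in ml and normalized by the intracranial
volume (`normalized_volume()`), which the package treats as a given input.
Manual mask editing is out of scope; `mask_diff()` supports QC instead.

## T1/T2 ratio mapping

Weighted-image intensities are in arbitrary scanner units, so the ratio is
only meaningful after each contrast is anchored to a common dimensionless
scale. `ratio_pipeline()`:

1. corrects smooth multiplicative inhomogeneity (`correct_bias()`): a
   degree-2 polynomial is fitted to log-intensities over a single-tissue
   mask and its exponential divided out globally. The fitting mask must be
   one spatially extended tissue class (the soft-tissue reference region is
   the default) - over a multi-class mask the polynomial absorbs anatomy
   rather than the bias field and degrades the calibration peaks. This
   polynomial corrector is a desk-scale, oracle-checkable component in its
   own right, exact for the log-polynomial fields the phantom generates;
2. detects each reference region's intensity peak as the mode of a
   Gaussian kernel density estimate on a 512-point grid
   (`histogram_peak()`, bandwidth 0.25 of the region's intensity SD);
3. maps the detected (bone, soft tissue, CSF) peaks onto fixed
   dimensionless anchors - (1.0, 0.6, 0.2) for T1w, (0.2, 0.6, 1.0) for
   T2w - by a monotone piecewise-linear function with linear extrapolation
   (`calibrate_intensities()`). The anchor values themselves are
   conventions: the downstream statistics only use monotone peak
   alignment, and the end-to-end ratio is invariant to independent
   positive rescaling of either input, which the tests assert. A smooth
   non-linear mapping would serve equally; piecewise-linear is exactly
   invertible and has no free shape parameters;
4. divides the calibrated volumes voxelwise where the denominator exceeds
   `1e-6` times its in-mask median, erodes the plexus mask by one voxel
   with the 6-connected structuring element (`erode_one_voxel()`) to
   shave partial-volume boundary voxels, and averages the ratio over the
   eroded mask (`compute_ratio()`). If erosion empties the mask the mean
   falls back to the un-eroded mask with a warning.

Rigid inter-contrast registration is out of scope: phantom pairs are
generated co-registered, and a grid mismatch is treated as an input error.

## The phantom generator

`make_phantom()` builds a head-like volume - bone shell, soft-tissue
interior, two curved tube-shaped ventricles, and a 6-connected frond-like
plexus grown by seeded region growth along the medial ventricular wall -
with reversed plexus/CSF contrast between T1w and T2w, a multiplicative
bias field (exponential of a random degree-2 polynomial rescaled to
$[1-a, 1+a]$), and additive Gaussian noise clipped at zero (a Rician
option exists; at the signal-to-noise ratios used the Gaussian
approximation keeps class means exact, which the oracle tests rely on).
Ventricle voxels adjacent to the wall or to the plexus carry partial-volume
mixtures (majority-CSF at the wall, so the plexus remains the brightest
ventricular content); these intermediate intensities are precisely what
the second clustering stage exists to strip, and without them a
three-component mixture would have nothing to do but split the homogeneous
plexus cluster. Class interiors - including every true plexus voxel - keep
exact class means, so noise-free phantoms have closed-form expected
outputs at every stage (segmentation Dice 1.0; calibrated ratio equal to
the anchor-mapped class-mean ratio).

What the phantom does not emulate: cortical anatomy, acquisition physics,
registration error, and lesions. Passing phantom tests therefore
demonstrates the correctness of the algorithms under their stated
assumptions, not clinical segmentation accuracy.

## The cohort generator

`sample_cohort()` generates subject-visit tables with the study's
structure: n = 422 subjects; 65% with a first follow-up (log-normal
around a 7.2-month median, jitter matched to the 6.0-9.6 IQR); 80/276 of
those with a second follow-up (19.2-month median, 18.0-22.8 IQR). Age is
Normal(40.8, 10.9); disease duration is Gamma with mean 9.5 and SD 17.4
years (the published SD exceeding the mean forces heavy right skew on a
non-negative support; shape is about 0.3), capped at 70 years; gender and
treatment class follow the published frequencies. Age and duration are
drawn independently - a handful of synthetic subjects may have durations
implausibly close to their age, which nothing downstream consumes.

Outcomes are built on a latent z-scale:

$$z_v(i,j) = g_v(d_{0i}) + \beta_t^{(v)} t_{ij} +
  \textstyle\sum_p \beta_{p \to v}\, z_p(i,j) +
  \textstyle\sum_b \beta_{b \times t \to v}\, z_b(i, 0)\, t_{ij} +
  u_i^{(v)} + e_{ij}^{(v)}$$

where $d_{0i}$ is baseline disease duration, $t_{ij}$ years since
baseline, $g_v$ the latent long-term curve (plexus volume: saturating
exponential reaching its plateau around 12 years with a subtle later
decline; T1/T2 ratio: a parabola with its nadir at 10 years; ventricle:
linear), and the $\beta$ are the published standardized coefficients,
used as the generating values. Each equation is centred on the baseline
cohort and its residual variance is chosen - and the realized noise draws
rescaled - so every variable's baseline z has unit variance; the
published coefficients are then partial standardized effects of the
generating equations and well-posed recovery targets. The subject random
intercept takes 85% of the residual variance (an intraclass correlation
typical of volumetric measures); EDSS is mapped from its latent z to the
0-10 half-point scale through a monotone quantile transform calibrated to
median 2.0, IQR 1.5-3.5. Dropout is independent of outcomes (no dropout
mechanism is published). Cognitive improvement over follow-up is encoded
as positive time slopes rather than separate practice terms.

Two generator design points deserve emphasis. First, the long-term curve
enters at *baseline* duration only: short-term within-subject change is
carried entirely by the calibrated time slopes. Letting the curve also
advance within subject would add its local derivative on top of the
published short-term slopes, and the mixed model's time coefficient would
then estimate neither quantity - the published value could never be
recovered, by construction. Anchoring at baseline makes each published
coefficient the exact estimand of the corresponding fitted model. Second,
free amplitudes were fixed once from feasibility under the duration
distribution: plexus curve amplitude 1.5 z; ratio parabola amplitude
0.1 z (its quadratic tail under the heavy-tailed durations already
contributes about a third of total variance - deeper dips are infeasible
under the unit-variance construction); ventricle slope 0.03 z/year; the
lateral-ventricle marginal (12, SD 6, x1000 normalized scale) is not
published and was set to a plausible value.

## Long-term trajectory estimation

`grace()` estimates a shared curve $g(d)$ over disease duration plus
mean-zero subject offsets $\alpha_i$ from short, staggered observations,
in the spirit of self-modeling regression built on alternating
conditional expectations. Outcomes are first rank-rescaled to (0,1) with
Hazen plotting positions (`ecdf_rescale()`), which puts different
variables on a common scale and makes the fit invariant to monotone
transforms of the outcome. The alternation is:

- offsets: $\alpha_i \leftarrow \frac{n_i}{n_i + \lambda}\,
  \overline{(y - g(d))}_i$, recentred to mean zero - the ridge form
  mimics a random-intercept BLUP with variance ratio $1/\lambda$
  (default $\lambda = 1$);
- curve: local-linear smooth with tricube weights of the
  offset-corrected data, bandwidth `bandwidth_frac` (default 0.3) times
  the observed duration range, evaluated on a 100-point grid.

Because the time axis is anchored to observed disease duration, no latent
subject-specific time shift is needed; the offsets-only model identifies
$g$ directly. Each iteration is accepted only if the mean squared
residual does not increase: the offsets of independent subjects carry no
duration information, so once they are absorbed, further alternation only
adds smoothing noise, and the first rejected iteration stops the fit
(this also makes the recorded objective path monotone by construction, a
property the tests assert). Convergence otherwise means the curve changed
by less than `tol = 1e-4` in sup-norm. Pointwise 95% bands come from 200
subject-level bootstrap resamples (resampling subjects, not observations,
respects within-subject correlation); the percentile band is widened,
where necessary, to contain the point estimate. A smoothing window
containing fewer than five observations raises an error advising a larger
bandwidth - with heavily skewed durations and small cohorts the far right
of the duration axis is genuinely sparse.

`find_turning_points()` reads the fitted curve: the slope by central
differences; the plateau onset as the first grid point after the steepest
point where the absolute slope drops below 10% of its maximum and stays
there for five grid points; the extremum as the interior global minimum
("nadir") or maximum ("peak") at least two grid points from either
boundary.

### A known limitation of the turning-point recovery

Under the study-calibrated conditions the plateau-onset and nadir
estimates do not recover the generating values, and the package reports
this honestly rather than adjusting the conditions. Two mechanisms
compound: (i) the default bandwidth, 0.3 of a duration range that extends
to about 67 years, is about 20 years - far wider than the 12-year rise it
must resolve - so the smoothed slope stays above the 10% threshold until
19-24 years even when the fit is applied to the exact noise-free
generating curve; (ii) rank-rescaling piles the many post-plateau
observations into a narrow band of the (0,1) scale, which keeps the
squashed curve's slope elevated past the rise. For the ratio nadir, the
feasible 0.1-z dip is far below the residual noise, and after rescaling
and smoothing the fitted curve is monotone with its minimum on the left
boundary: no interior nadir exists to detect (on the noise-free curve the
rule does find it, near 8 years). Recovering the generating values within
a couple of years would need a bandwidth fraction around 0.1 and a deeper
generating dip; both are fixed as study conditions, so the corresponding
acceptance checks fail and are documented as such rather than loosened.

## Association layer

`fit_cross_sectional()` runs ordinary least squares of the z-scored
outcome on the z-scored predictor plus covariates on baseline rows;
`fit_longitudinal()` fits linear mixed models with a random intercept per
subject by maximum likelihood (nested fixed-effect comparisons stay
valid under ML, and Wald intervals match the beta-plus-SE reporting
convention), with follow-up time in years and optional
baseline-measure-by-time interactions (main effects always included).
Covariates are age, gender, disease duration and treatment class
throughout; EDSS is modelled as continuous, as its published standardized
coefficients imply. Two conventions matter for recovery and are the
package's own choices where the published text is ambiguous:

- continuous variables (including the baseline measure of an interaction)
  are standardized against the *baseline-visit* distribution, one row per
  subject. All-row SDs are inflated by follow-up change, shrinking time
  effects several percent, and all-row standardization of a merged
  baseline covariate would over-weight multi-visit subjects. Categorical
  covariates are dummy-coded unstandardized;
- longitudinal models adjust for *baseline* disease duration: duration at
  assessment equals baseline duration plus time, so inside a model that
  already contains time it is within-subject collinear with it, and the
  collinearity leaks the cohort-level duration trend into the time
  coefficient. Cross-sectional models use duration at assessment, which
  at baseline is the same quantity.

`stepwise_select()` is bidirectional p-value stepwise selection (enter
below 0.05, remove above 0.10, covariates always retained, candidates
scanned in ascending current p-value, making the procedure
deterministic); the published text names no criteria, so these common
clinical-statistics defaults are exposed in `analysis_config()`.
`bh_fdr()` applies Benjamini-Hochberg step-up adjustment within one
family per results table (the published correction never enumerates its
families; per-table is the natural reading and is recorded in the
output); stepwise results are exempt, as selection invalidates the
independence of its p-values. `annualized_change()` averages per-interval
changes per year across a subject's consecutive intervals; a single visit
yields `NA`.

## Problem sizes and determinism

All simulations are seeded and bit-reproducible; `with_seed()` restores
the caller's RNG state. The test suite runs on phantoms of 48 x 56 x 44
voxels, cohorts of n = 422 (the study size), one large self-consistency
cohort of n = 20,000 baseline records, and replicate batches of 40-100
seeded cohorts for type-I-error, coverage and selection-rate checks;
bootstrap bands use 200 resamples (50 in unit tests). These sizes were
chosen so each check has the statistical resolution its tolerance
requires.

## Known limitations

- The piecewise-linear intensity calibration is a declared stand-in for
  the cited toolbox's smooth non-linear mapping, not a reimplementation
  of it.
- The polynomial bias corrector is exact for log-polynomial fields, a
  simplification of spline-based correctors; it needs a single-class
  fitting mask.
- The offsets-only trajectory model omits subject-specific time shifts;
  with the time axis anchored to disease duration they are unnecessary,
  but trajectories with genuine phase variation across subjects would
  need them.
- The generator draws dropout independently of outcomes and encodes
  effects as exact linear partial coefficients; real cohorts are not that
  clean, so recovery results certify the estimators, not robustness to
  model misspecification.
- Turning-point recovery under the study-calibrated smoother is biased
  late for the plateau and infeasible for the shallow ratio nadir, as
  detailed above.
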