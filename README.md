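# plexdyn

Choroid plexus dynamics from longitudinal structural MRI.

The choroid plexus (ChP) — the CSF-producing epithelium inside the brain
ventricles — is an immune gateway implicated in multiple sclerosis, and
its enlargement is a candidate biomarker of disease activity. Tracking it
requires several pieces of computational machinery that this package
implements as reusable, tested components for neuroimaging statisticians:

- **Segmentation** (`segment_chp()`): a two-stage intensity-clustering
  procedure inside a lateral-ventricle mask. A two-component Gaussian
  mixture over in-ventricle T1w intensities separates CSF from brighter
  voxels; the bright cluster is smoothed with the SUSAN structure-preserving
  filter (σ = 1 mm), and a three-component mixture over the smoothed
  intensities keeps the highest-mean component as the final ChP mask.
  Volumes are reported in ml and normalized by intracranial volume (NChPV).
- **T1/T2 ratio mapping** (`ratio_pipeline()`): both contrasts are
  bias-corrected, calibrated by mapping the histogram peaks of bone, soft
  tissue and CSF reference regions onto fixed dimensionless anchors, and
  divided voxelwise; the mean ratio is extracted over the one-voxel-eroded
  ChP mask to limit partial-volume contamination.
- **Long-term trajectories** (`grace()`): a self-modeling
  (alternating-conditional-expectations style) estimator of a shared curve
  g(d) over disease duration d plus ridge-shrunken subject offsets αᵢ,
  fitted to ECDF-rescaled outcomes from short staggered follow-ups:
  y(i,j) = g(d(i,j)) + αᵢ + ε. Tricube local-linear smoothing, subject-level
  bootstrap bands, and turning-point detection (plateau onset, nadir).
- **Association layer**: standardized cross-sectional OLS
  (`fit_cross_sectional()`), random-intercept linear mixed models with
  time and baseline×time terms fitted by ML with Wald intervals
  (`fit_longitudinal()`), deterministic bidirectional stepwise selection
  (`stepwise_select()`), Benjamini–Hochberg correction (`bh_fdr()`), and
  annualized change (`annualized_change()`).
- **Synthetic ground truth**: a phantom-image generator
  (`make_phantom()`) and a longitudinal cohort generator
  (`sample_cohort()`) whose defaults are calibrated to a published
  422-patient relapsing-remitting MS cohort (marginals, visit structure
  with dropout, latent non-linear disease-course curves, standardized
  effect sizes), so every stage is testable without patient data.

## Worked example

```r
library(plexdyn)

# a synthetic T1w/T2w pair with known ground truth
p   <- make_phantom(phantom_spec(seed = 7))
seg <- segment_chp(p$t1w, p$ventricle_mask, p$voxel_dims, p$icv_ml)
rr  <- ratio_pipeline(p$t1w, p$t2w, seg$mask, p$ref_masks)

# a study-calibrated synthetic cohort
ch <- sample_cohort(cohort_spec(seed = 1))
r  <- fit_longitudinal("nchpv", ch)           # NChPV change over follow-up
f  <- grace(nchpv ~ duration_years | subject_id, ch, rescale = "ecdf")
```

This prints (seed-for-seed):

```
ChP volume: 0.520 ml | normalized x1000: 15.819 | Dice vs truth: 0.955
mean ChP T1/T2 ratio: 0.704

       term beta_std     se ci_lo ci_hi       p
 time_years     0.43 0.0232 0.384 0.475 2.2e-76

Long-term trajectory fit (alternating self-modeling regression)
  771 observations, 422 subjects
  duration range: 0.00 - 72.56 years; bandwidth 21.77 years
  outcome rescale: ecdf
  11 iterations, converged: TRUE, final MSR 0.012296
```

Reading the numbers: the segmentation recovers the 0.5-ml synthetic
plexus at Dice 0.955 under default noise; the calibrated ratio (0.704)
matches the phantom's anchor-mapped class-mean ratio (0.692) within 2%;
the mixed model estimates a standardized NChPV increase of 0.43 per year
of follow-up against a generating value of 0.45 — inside two standard
errors; and the trajectory object carries the fitted disease-course curve
with its bootstrap band (`plot(f)`, `summary(f)`).

A command-line front end wrapping the same functions ships at
`inst/cli/plexdyn.R` (subcommands `simulate-phantom`, `segment`, `ratio`,
`simulate-cohort`, `trajectory`, `associations`, `run-full`).

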