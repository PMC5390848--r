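---
title: "Data-driven ROIs for longitudinal brain atrophy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven ROIs for longitudinal brain atrophy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophyROI)
```

## The problem

Serial structural MRI yields, per subject, a voxelwise map of the annual
rate of relative volume change (units 1/year; negative values mean tissue
contraction). In progressive neurodegeneration — the motivating case is the
frontotemporal lobar degeneration (FTLD) spectrum with its bvFTD, svPPA and
nfvPPA variants — these rate maps carry the disease signal that a clinical
trial would try to slow. The power of such a trial depends on the effect
size of the chosen summary measure: the mean annual change over a region of
interest (ROI), standardized as a Cohen's d between patients and controls.
An anatomically fixed a priori ROI (frontal lobe, temporal lobe, whole gray
matter) dilutes the signal with unaffected tissue; this package derives the
ROI from the data, while protecting the resulting effect size from
optimistic bias through cross-validation.

`atrophyROI` operates strictly downstream of registration: its inputs are
rate maps on a common grid (the upstream pairwise longitudinal registration,
tissue segmentation and spatial normalization belong to dedicated
neuroimaging toolchains and are out of scope). Inputs are NIfTI-1 volumes
listed in a CSV manifest (`subject_id, group, interval_years, path`); maps
are annualized by dividing by the interscan interval and multiplied
voxelwise by a gray-matter probability map. Voxels whose gray-matter
probability falls below an inclusion threshold (default 0.1) are excluded
from all statistics — the probability-weighting alone would otherwise let
near-zero-probability voxels enter the t maps with spuriously deflated
variance. No spatial smoothing is applied anywhere in the pipeline.

## The ROI-optimization procedure

For one train/test split, with patients \(P\) and controls \(C\):

1. **Voxelwise Welch t map.** At every analysis-mask voxel,
   \(t = (\bar x_P - \bar x_C) / \sqrt{s_P^2/n_P + s_C^2/n_C}\) with
   Welch–Satterthwaite degrees of freedom. Faster contraction in patients
   gives negative t. Voxels with zero variance in both groups have no
   defined t and are dropped from the mask (and counted).
2. **Threshold sweep.** Candidate ROIs are formed at every cutoff from 3.5
   to the maximum observed contraction-direction |t| in steps of 0.01.
   Candidates are restricted to the contraction side (negative t, negative
   patient mean rate): expanding voxels usually reflect residual CSF, and a
   generalizable ROI should not depend on segmentation leftovers. ROIs
   smaller than `minRoiVoxels` (default 10; set 1 for the strictest
   behaviour) are skipped.
3. **Effect-size curve.** For each cutoff, every subject is reduced to the
   mean rate over the ROI and Cohen's d is computed with the classic
   df-weighted pooled SD. The pooled estimator is used deliberately even
   though the t map allows unequal variances: the unequal-variance choice
   affects only the voxel ranking, while "Cohen's d" names the conventional
   pooled statistic. d keeps its sign (negative = faster patient
   contraction); the sweep is reported as an `EffectSizeCurve`.
4. **Smoothed-maximum threshold selection.** At high cutoffs only a handful
   of voxels survive and the empirical d becomes unstable, so the raw
   argmax is unreliable. The heuristic: iteratively truncate the
   high-threshold end of the curve — excluding from 0% up to 10% of the
   highest-|t| candidate voxels, stepping the exclusion along the sweep
   grid — lowess-smooth |d| against threshold on each truncated curve
   (span 0.3, one robustness iteration; both configurable), record the
   threshold of each smoothed maximum, and take the median (ties and
   even-length medians resolve to the lower threshold, which also keeps the
   result on the sweep grid). Curves with fewer than 5 points fall back to
   the raw argmax.
5. **Unbiased test effect size.** The selected ROI is frozen and applied to
   the held-out test subjects; their Cohen's d is the partition's unbiased
   effect-size estimate.

Steps 1–5 repeat over stratified random partitions (default 1,024; the
worked examples in this package use 128 at desk scale). Each partition
assigns round(0.16 × N) subjects to the test set, with the patient count
drawn uniformly from the integers strictly between 1/3 and 2/3 of the test
size. The summary is the mean test d with a normal-theory 95% CI
(mean ± 1.96·sd/√k over the k successful partitions; a percentile CI would
also be defensible — the printed CIs in this literature are narrow enough
that the choice is immaterial, and normal theory matches their width).
Partitions where no voxel reaches the starting threshold are recorded as
failures and excluded from the mean; their count is reported.

**Consensus ROI.** Each voxel's weight is the proportion of partitions
whose optimal ROI contains it, with partitions weighted by |test d|:
\(w(v) = \sum_k |d_k| \, \mathbf 1[v \in \mathrm{ROI}_k] / \sum_k |d_k|\).
Weighting by the held-out (not training) effect size was an open choice; the
test-set d is used because it is the quantity the procedure certifies. When
every |d_k| is zero the unweighted proportion is used.

**Sample sizes.** For a 1:1 placebo-controlled trial whose treatment slows
the annual change by a fraction r (0.2 and 0.4 are the conventional
scenarios), the standardized treated-vs-placebo difference is
\(\delta = r\,|d|\); anchoring the SD on the patient group is inherited
from d itself. `nPerArm()` returns the smallest per-arm n at which the
two-sided two-sample t test reaches the design power, computed exactly with
the noncentral t distribution (a normal-approximation mode exists and
brackets the exact answer within a subject or two). Fed with the published
FTLD mean test effect sizes (−0.98, −1.84, −3.45) this reproduces the
published per-arm sample sizes to within one subject — the residual ±1
comes from the effect sizes being printed to two decimals.

**Peak dispersion.** Per subject, the peak is the voxel with the most
negative (optionally neighborhood-averaged) rate inside the mask, ties
resolving to the lowest linear voxel index; dispersion is the mean pairwise
distance between peaks in world mm, so it is grid-independent. Dispersion
quantifies how consistently a variant atrophies in the same place — the
proposed explanation for why tightly localized variants support much
smaller trials.

## The synthetic cohort generator

No real cohort ships with the package; the generator produces rate-map
cohorts with the statistical structure the analysis assumes, plus ground
truth, so every stage is testable. A subject's map is

\(x_i(v) = g_i + \varepsilon_i(v) + \sum_f w_f(v - s_i)\,[\mu_f + \sigma_f\,h_i(v)]\)

- \(g_i\): per-subject whole-map rate offset, N(controlDriftMean,
  subjectDriftSd²). Real Jacobian rate maps show such global offsets
  (hydration, scanner drift, normal aging variability).
- \(\varepsilon_i\): i.i.d. voxel noise, SD `voxelNoiseSd` (an optional
  smoothing FWHM can correlate it; off by default since the analysis never
  smooths).
- Each focus f is a sphere (or Gaussian-falloff ball) of radius
  `radiusMm` around a nominal centre, with mean rate \(\mu_f\) (1/year,
  negative) and between-subject SD \(\sigma_f\).
- \(h_i\): a unit-variance Gaussian random field (FWHM
  `heterogeneityFwhmMm`, default 6 mm; the presets use 3 mm) drawn per
  patient — within-region
  heterogeneity of atrophy. A spatially varying draw, rather than one
  scalar per focus, is essential: with a scalar draw the ROI-mean signal
  and its between-subject SD scale together, ROI dilution becomes free, and
  the effect-size-vs-threshold curve degenerates to a monotone ramp that no
  maximum-selection heuristic can use.
- \(s_i\): one rigid 3-D translation per subject, N(0, jitterSdMm² I) —
  the between-subject variability in atrophy *location*. Jittered centres
  leaving the grid are clipped with a warning.

Ground truth records the per-subject realized centres, the planted mask
(union of nominal foci; for Gaussian falloff, profile > 0.5) and the
realized planted effect size (Cohen's d of the planted-mask mean change in
the generated cohort).

Three presets mimic the qualitative structure of the FTLD variants on a
32×32×32 grid at 1.5 mm with 30 + 30 subjects (sized so the full
cross-validation runs in seconds to minutes on one CPU): `svPPA-like` (one
compact focus, rate −0.030/yr, jitter 1 mm), `nfvPPA-like` (two foci,
−0.026/yr, jitter 2.5 mm) and `bvFTD-like` (three dispersed foci,
−0.018/yr, jitter 6 mm); all share voxel noise 0.003/yr, subject drift SD
0.009/yr and heterogeneity SD 0.018/yr. The rates and SDs were calibrated
once against the planted-mask effect size so the presets span planted d of
roughly −3 to −0.9, the order of the published variant effect sizes, and
were then frozen. The test suite verifies that the cross-validated mean
test d reproduces the planted effect size within its CI, that the
effect-size ordering svPPA > nfvPPA > bvFTD in magnitude and the
peak-dispersion ordering bvFTD > nfvPPA > svPPA both hold across seeds, and
that on signal-free cohorts the held-out effect size is unbiased while the
training effect size is strongly selection-biased.

```{r presets, eval = FALSE}
spec <- variantPreset("svPPA-like", seed = 1)
g <- generateCohort(spec)
cohort <- applyGMMask(g$cohort, g$gm)
cv <- runCV(cohort, "svPPA", spec = partitionSpec(nIterations = 128, seed = 1))
cv
```

## What the synthetic data do and do not show

The generator emulates focal contraction with realistic between-subject
variability in amplitude and location, global rate offsets, i.i.d.
measurement noise and soft gray-matter boundaries. It does **not** emulate
registration error, intensity artifacts, spatially structured noise,
anatomically shaped (non-spherical) atrophy, or cortical topology. Passing
tests therefore certify the statistical machinery — stratification,
sweep, selection, cross-validation bookkeeping, weighting, power
arithmetic — not the anatomical validity of ROIs on real data.

One desk-scale limitation deserves emphasis. With 30 + 30 subjects a
training partition contains about 50 maps, and several hundred voxels pass
the 3.5 starting threshold; selecting a threshold by maximizing the
training-set d over that many exchangeable candidates is dominated by
selection bias (of order \(\sqrt{2\log(N/k)/n}\) in d units), so the
smoothed-maximum heuristic settles on compact ROIs of roughly the top few
percent of candidate voxels rather than the full planted extent. The
held-out effect sizes remain honest — that is the point of the
cross-validation — but the consensus ROI under-covers the planted mask at
this cohort size. At the cohort sizes of real studies (around 100 training
maps and hundreds of thousands of voxels with spatially graded true
effects) the curve's interior maximum is genuine and the same heuristic
recovers anatomically extended ROIs. The acceptance suite states the
planted-mask overlap check at the strict Dice ≥ 0.5 level regardless, and
it fails at desk scale by design rather than being weakened.

## Numerical choices and edge cases

- Test-set size rounding: nearest integer (141 × 0.16 = 22.56 → 23);
  stratification bounds are strict inequalities.
- All randomness derives from one master seed; every CV iteration uses its
  own derived substream, so results are independent of execution order and
  bit-identical across reruns.
- Lowess: span 0.3 of curve points, one robustness iteration; smoothed-max
  ties resolve to the lower threshold within 1e-10.
- `roiAtThreshold` and the sweep signal classed `noROIError` conditions so
  callers can distinguish "no informative voxels" from real errors.
- Zero pooled SD makes Cohen's d an error rather than an Inf.
- Sample-size search: bracket by doubling, then bisect; cap 10^6 per arm
  (flagged when hit); the reported achieved power is the noncentral-t power
  at the returned n.
- NIfTI round-trips use float64 for rate maps (bit-exact), float32 for
  consensus maps, uint8 for masks; grids carry the full voxel-to-world
  affine, and world coordinates use 0-based voxel indices.
- Peak detection defaults to the raw voxel argmin. On unsmoothed synthetic
  maps the argmin of i.i.d. noise is an extreme-value statistic, so the
  dispersion analyses in the tests pass a 3 mm averaging neighborhood;
  real rate maps are spatially structured and need no such stabilizer.

## Known limitations

- The pipeline certifies effect sizes for the *measured* contrast
  (patients vs controls over 1 year); trial sample sizes inherit the
  simplifying assumptions of a two-arm t test on annualized change
  (no dropout, no covariates, no longitudinal mixed modeling).
- Clinical-score sample sizes are accepted as external constants for
  comparison tables; fitting the underlying longitudinal clinical models is
  out of scope.
- Consensus weights have no significance calibration; thresholding them is
  descriptive.
- Sensitivity analyses on subgroups are expressed by subsetting the cohort
  and rerunning — no dedicated machinery exists or is needed.
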