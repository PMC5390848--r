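# atrophyROI

Data-driven regions of interest (ROIs) for longitudinal brain-volume
change, with cross-validated effect sizes and clinical-trial sample-size
estimation.

## The problem

Serial MRI yields per-subject maps of the annual rate of relative volume
change (1/year; negative = tissue contraction). Trials in progressive
neurodegeneration — the motivating case is the frontotemporal lobar
degeneration spectrum (bvFTD, svPPA, nfvPPA) — need an outcome measure with
a large patient-vs-control effect size, because the per-arm sample size for
detecting a fractional slowing *r* of the annual change scales like
1/(r·d)². A priori anatomical ROIs (frontal, temporal, whole gray matter)
dilute the disease signal with unaffected tissue. This package derives the
ROI from the data while keeping the certified effect size honest:

1. voxelwise Welch t map, patients vs controls, on gray-matter-masked
   annualized rate maps (t = (x̄_P − x̄_C)/√(s²_P/n_P + s²_C/n_C), negative
   where patients contract faster);
2. candidate ROIs by sweeping the t cutoff from 3.5 to the observed maximum
   in 0.01 steps (contraction side only);
3. Cohen's d (pooled SD) of the ROI-mean rate at every cutoff — the
   effect-size-vs-threshold curve;
4. threshold selection by a smoothed-maximum heuristic (lowess over the
   curve after iteratively excluding 0–10 % of the highest-t voxels; median
   of the smoothed maxima);
5. unbiased effect size from held-out test subjects, over many stratified
   train/test partitions (default 1,024; 16 % test fraction, patient share
   strictly between 1/3 and 2/3);
6. an effect-size-weighted consensus map,
   w(v) = Σ_k |d_k| 1[v ∈ ROI_k] / Σ_k |d_k|;
7. per-arm sample sizes from the mean test d via the exact noncentral-t
   power of a two-sided two-sample t test (α = 0.05, power = 0.8, 1:1);
8. per-subject peak-atrophy localization and cross-subject dispersion
   (mean pairwise distance, mm) — the spatial-heterogeneity readout that
   tracks inversely with the achievable effect size.

No patient data ship with the package: a synthetic cohort generator plants
spherical atrophy foci with controllable amplitude heterogeneity and
spatial jitter, and returns the ground truth needed to validate every
stage (see the methods vignette, `vignettes/data-driven-atrophy-rois.Rmd`).

## Worked example

```r
library(atrophyROI)

spec   <- variantPreset("svPPA-like", seed = 1)   # 30 HC + 30 patients, 32^3 grid
g      <- generateCohort(spec)
cohort <- applyGMMask(g$cohort, g$gm)
cohort
#> RateMapCohort: 60 subjects (HC=30, svPPA=30) on 32x32x32 grid
#>   analysis mask: 12400 voxels

cv <- runCV(cohort, "svPPA", spec = partitionSpec(nIterations = 128, seed = 1))
cv
#> CVResult: mean test d = -3.029 (95% CI [-3.216, -2.843]) over 128 iterations (0 failed)

g$truth$plantedEffectSize      # ground truth the CV should recover
#> [1] -2.62

nPerArm(cv@meanTestD, TrialDesign(reduction = 0.4))
#> SampleSizeResult: n = 12 per arm (noncentral-t, achieved power 0.810)

pk <- peakLocations(cohort, neighborhoodRadiusMm = 3)
peakDispersion(pk[pk$group == "svPPA", ])
#> [1] 6.9   # mm
```

The cross-validated mean test effect size (−3.03) recovers the planted
ground truth (−2.62) within its Monte-Carlo spread, and converts into a
12-patients-per-arm trial for a 40 % slowing — the same arithmetic that
turns the published variant effect sizes (−0.98, −1.84, −3.45) into 103,
31 and 10 patients per arm.

A command-line front end wrapping the same functions is installed at
`inst/scripts/atrophyroi.R` (subcommands `simulate`, `tmap`, `cv`, `power`,
`peaks`).

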