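Package: atrophyROI
Title: Data-Driven Regions of Interest for Longitudinal Brain Atrophy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives data-driven regions of interest (ROIs) for voxelwise
    longitudinal brain-volume change by cross-validated effect-size
    optimization. Annualized relative volume-change maps are compared between
    patient and control groups with voxelwise Welch t statistics; candidate
    ROIs are formed by sweeping the t threshold, the threshold maximizing
    Cohen's d on the training partition is selected with a lowess-based
    smoothed-maximum heuristic, and unbiased effect sizes are estimated on
    held-out test partitions across many stratified splits. The package also
    aggregates an effect-size-weighted consensus ROI, converts effect sizes
    into per-arm clinical-trial sample sizes via the noncentral t
    distribution, quantifies cross-subject dispersion of peak atrophy, and
    ships a synthetic change-map cohort generator with planted ground truth
    so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
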