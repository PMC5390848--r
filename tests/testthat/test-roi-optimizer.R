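test_that("thresholding extracts contraction-side voxels and nests", {
    ts <- tinyTStat(c(-4.0, -3.4, -5.0))
    cfg <- sweepConfig(minRoiVoxels = 1L)
    roi <- roiAtThreshold(ts, 3.5, cfg)
    expect_equal(which(as.vector(roi)), c(1L, 3L))
    # nesting: higher threshold is a subset
    roi4 <- roiAtThreshold(ts, 4.5, cfg)
    expect_true(all(which(as.vector(roi4)) %in% which(as.vector(roi))))
    # above the maximum |t| there is no ROI
    expect_error(roiAtThreshold(ts, 6, cfg), class = "noROIError")
    expect_error(roiAtThreshold(ts, 1, cfg), "tStart")
    # expanding voxels (t > 0) never qualify under contraction-only
    ts2 <- tinyTStat(c(4.0, -3.6, 5.0))
    expect_equal(which(as.vector(roiAtThreshold(ts2, 3.5, cfg))), 2L)
})

test_that("Cohen's d matches the pooled-SD hand computation", {
    # single-voxel maps so subject scalars equal the stated values
    ctl <- c(0, 0, 1, -1); pat <- c(-2, -2)
    co <- tinyCohort(rbind(c(ctl, pat)),
                     groups = c(rep("HC", 4), rep("PAT", 2)))
    roi <- array(TRUE, c(1, 1, 1))
    expect_equal(cohensD(roi, co, "PAT"), oracleCohenD(pat, ctl),
                 tolerance = 1e-12)
    expect_equal(cohensD(roi, co, "PAT"), -2 / sqrt(0.5), tolerance = 1e-12)

    # equal group means give d = 0
    co0 <- tinyCohort(rbind(c(0, 1, 1, 0)), groups = rep(c("HC", "PAT"), 2))
    expect_equal(cohensD(array(TRUE, c(1, 1, 1)), co0, "PAT"), 0)

    # scale invariance and subject-relabelling invariance
    vals <- matrix(rnorm(3 * 8), 3, 8)
    grp <- rep(c("HC", "PAT"), each = 4)
    co1 <- tinyCohort(vals, grp)
    roi3 <- array(c(TRUE, FALSE, TRUE), c(3, 1, 1))
    d1 <- cohensD(roi3, co1, "PAT")
    expect_equal(cohensD(roi3, tinyCohort(5 * vals, grp), "PAT"), d1)
    perm <- c(4:1, 8:5)
    expect_equal(cohensD(roi3, tinyCohort(vals[, perm], grp[perm]), "PAT"),
                 d1)

    expect_error(cohensD(array(FALSE, c(3, 1, 1)), co1, "PAT"), "empty")
    coz <- tinyCohort(rbind(c(1, 1, 2, 2)), groups = rep(c("HC", "PAT"), each = 2))
    expect_error(cohensD(array(TRUE, c(1, 1, 1)), coz, "PAT"), "pooled SD")
})

test_that("the sweep produces a structurally valid effect-size curve", {
    g <- generateCohort(smallSignalSpec(seed = 13L))
    co <- applyGMMask(g$cohort, g$gm)
    ts <- welchTMap(co, "PAT")
    cu <- effectSizeSweep(ts, co, "PAT")
    df <- as.data.frame(cu)
    expect_gt(nrow(df), 5)
    expect_equal(df$threshold[1], 3.5)
    expect_true(all(diff(df$threshold) > 0))
    expect_true(all(diff(df$n_voxels) <= 0))
    expect_lte(max(df$threshold), max(abs(ts@t[ts@mask])))
    # curve d values equal direct recomputation at spot-checked thresholds
    cfg <- sweepConfig()
    for (i in c(1L, nrow(df) %/% 2L, nrow(df))) {
        roi <- roiAtThreshold(ts, df$threshold[i], cfg)
        expect_equal(sum(roi), df$n_voxels[i])
        expect_equal(cohensD(roi, co, "PAT"), df$d[i], tolerance = 1e-12)
    }
})

test_that("pure-noise cohorts yield no informative voxels at t >= 3.5", {
    spec <- SyntheticSpec(grid = tinyGrid(c(10L, 10L, 10L)),
                          nControls = 8L, nPatients = 8L, foci = list(),
                          voxelNoiseSd = 0.01, subjectDriftSd = 0.005,
                          seed = 17L)
    g <- generateCohort(spec)
    co <- applyGMMask(g$cohort, g$gm)
    ts <- welchTMap(co, "custom")
    expect_error(effectSizeSweep(ts, co, "custom"), class = "noROIError")
    expect_error(optimizeTrainingROI(ts, co, "custom"), class = "noROIError")
})

test_that("smoothed maximum honours monotone, constant and unimodal curves", {
    mkCurve <- function(th, d, n) new("EffectSizeCurve", thresholds = th,
                                      effectSizes = d,
                                      voxelCounts = as.integer(n))
    th <- seq(3.5, 6.5, by = 0.01)
    k <- length(th)
    # strictly decreasing |d|: the lowest threshold wins
    dec <- mkCurve(th, -seq(2, 1, length.out = k), round(seq(500, 10, length.out = k)))
    expect_equal(smoothedMaximum(dec), 3.5)
    # constant |d|: tie-break to the lowest threshold
    cst <- mkCurve(th, rep(-1.5, k), round(seq(500, 10, length.out = k)))
    expect_equal(smoothedMaximum(cst), 3.5)
    # noiseless unimodal curve peaks near its true maximum
    peak <- 4.8
    uni <- mkCurve(th, -(2 - ((th - peak) / 1.3)^2),
                   round(seq(500, 10, length.out = k)))
    expect_lt(abs(smoothedMaximum(uni) - peak), 0.5)
    # tiny curves fall back to the raw argmax
    short <- mkCurve(c(3.5, 3.6, 3.7), c(-1, -3, -2), c(30L, 20L, 10L))
    expect_equal(smoothedMaximum(short), 3.6)
    # stability under a 1e-12 perturbation of every d
    uni2 <- mkCurve(th, uni@effectSizes + 1e-12,
                    round(seq(500, 10, length.out = k)))
    expect_equal(smoothedMaximum(uni2), smoothedMaximum(uni))
})

test_that("training-ROI optimization is deterministic and focus-precise", {
    g <- generateCohort(smallSignalSpec(seed = 19L))
    co <- applyGMMask(g$cohort, g$gm)
    ts <- welchTMap(co, "PAT")
    r1 <- optimizeTrainingROI(ts, co, "PAT")
    r2 <- optimizeTrainingROI(ts, co, "PAT")
    expect_identical(r1@threshold, r2@threshold)
    expect_identical(r1@mask, r2@mask)
    expect_gte(r1@nVoxels, 10L)
    # the selected ROI concentrates on the planted focus
    planted <- as.vector(g$truth$plantedMask)
    precision <- sum(as.vector(r1@mask) & planted) / sum(r1@mask)
    expect_gte(precision, 0.8)
    # its training d matches the curve value at the selected threshold
    expect_equal(r1@trainingD, cohensD(r1@mask, co, "PAT"), tolerance = 1e-12)
})
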