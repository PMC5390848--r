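test_that("degenerate spec with no foci and no noise gives all-zero maps", {
    spec <- SyntheticSpec(grid = tinyGrid(), nControls = 2L, nPatients = 2L,
                          foci = list(), voxelNoiseSd = 0,
                          subjectDriftSd = 0, controlDriftMean = 0)
    g <- generateCohort(spec)
    expect_true(all(rateMatrix(g$cohort) == 0))
})

test_that("the generator is seed-deterministic", {
    spec <- smallSignalSpec(seed = 5L, nPerGroup = 4L)
    a <- generateCohort(spec)
    b <- generateCohort(spec)
    expect_identical(rateMatrix(a$cohort), rateMatrix(b$cohort))
    expect_identical(a$truth$plantedEffectSize, b$truth$plantedEffectSize)

    spec2 <- smallSignalSpec(seed = 6L, nPerGroup = 4L)
    expect_false(identical(rateMatrix(a$cohort),
                           rateMatrix(generateCohort(spec2)$cohort)))
})

test_that("planted focal rate is recovered in expectation inside the focus", {
    spec <- SyntheticSpec(grid = VoxelGrid(c(16L, 16L, 16L), 1.5),
                          nControls = 10L, nPatients = 50L,
                          foci = list(AtrophyFocus(c(0, 0, 0), 5, -0.03, 0)),
                          jitterSdMm = 0, voxelNoiseSd = 0.001,
                          subjectDriftSd = 0, seed = 21L)
    g <- generateCohort(spec)
    inFocus <- as.vector(g$truth$plantedMask)
    grp <- groups(g$cohort)
    diff <- rowMeans(rateMatrix(g$cohort)[inFocus, grp == "custom"]) -
            rowMeans(rateMatrix(g$cohort)[inFocus, grp == "HC"])
    # 3 * SEM of the mean in-focus group difference under the stated noise
    sem <- 0.001 * sqrt(1 / 50 + 1 / 10) / sqrt(sum(inFocus))
    expect_lt(abs(mean(diff) - (-0.03)), 3 * sem)
})

test_that("noise-free, jitter-free cohorts show the exact planted difference", {
    spec <- SyntheticSpec(grid = tinyGrid(c(12L, 12L, 12L)),
                          nControls = 3L, nPatients = 3L,
                          foci = list(AtrophyFocus(c(0, 0, 0), 4, -0.02, 0)),
                          jitterSdMm = 0, voxelNoiseSd = 0,
                          subjectDriftSd = 0, seed = 2L)
    g <- generateCohort(spec)
    grp <- groups(g$cohort)
    diff <- rowMeans(rateMatrix(g$cohort)[, grp == "custom"]) -
            rowMeans(rateMatrix(g$cohort)[, grp == "HC"])
    inFocus <- as.vector(g$truth$plantedMask)
    expect_true(all(diff[inFocus] == -0.02))
    expect_true(all(diff[!inFocus] == 0))
})

test_that("jittered foci leaving the grid are clipped with a warning", {
    spec <- SyntheticSpec(grid = tinyGrid(c(8L, 8L, 8L)),
                          nControls = 2L, nPatients = 6L,
                          foci = list(AtrophyFocus(c(4.5, 0, 0), 2, -0.02, 0)),
                          jitterSdMm = 6, voxelNoiseSd = 0,
                          subjectDriftSd = 0, seed = 4L)
    expect_warning(generateCohort(spec), "clipped")
})

test_that("variant presets validate and order jitter svPPA < nfvPPA < bvFTD", {
    sv <- variantPreset("svPPA-like")
    nf <- variantPreset("nfvPPA-like")
    bv <- variantPreset("bvFTD-like")
    for (s in list(sv, nf, bv)) expect_true(validObject(s))
    expect_lt(sv@jitterSdMm, nf@jitterSdMm)
    expect_lt(nf@jitterSdMm, bv@jitterSdMm)
    expect_error(variantPreset("unknown"), "arg")
    # focal rates are contractions and planted masks non-trivial
    expect_true(all(vapply(bv@foci, function(f) f@meanRate < 0, logical(1))))
})

test_that("synthetic gray matter is a valid probability map with a soft edge", {
    gm <- syntheticGrayMatter(VoxelGrid(c(16L, 16L, 16L), 1.5))
    p <- gm@probabilities
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(sum(p == 1), 0)              # solid core
    expect_gt(sum(p == 0), 0)              # background
    expect_gt(sum(p > 0 & p < 1), 0)       # soft edge exercised
})

test_that("generateCohort writes volumes, manifest and ground-truth sidecar", {
    dir <- withr::local_tempdir()
    g <- generateCohort(smallSignalSpec(seed = 9L, nPerGroup = 3L), dir = dir)
    expect_true(file.exists(file.path(dir, "manifest.csv")))
    expect_true(file.exists(file.path(dir, "gm.nii.gz")))
    expect_true(file.exists(file.path(dir, "planted_roi.nii.gz")))
    gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
    expect_equal(gt$patient_group, "PAT")
    expect_equal(gt$planted_effect_size, g$truth$plantedEffectSize,
                 tolerance = 1e-12)
    planted <- readVolume(file.path(dir, "planted_roi.nii.gz"))
    expect_equal(as.vector(planted$values) > 0,
                 as.vector(g$truth$plantedMask))
})

test_that("optional noise smoothing induces spatial autocorrelation", {
    base <- SyntheticSpec(grid = tinyGrid(c(12L, 12L, 12L)),
                          nControls = 2L, nPatients = 2L, foci = list(),
                          voxelNoiseSd = 0.01, subjectDriftSd = 0, seed = 8L)
    smooth <- SyntheticSpec(grid = tinyGrid(c(12L, 12L, 12L)),
                            nControls = 2L, nPatients = 2L, foci = list(),
                            voxelNoiseSd = 0.01, subjectDriftSd = 0,
                            smoothFwhmMm = 6, seed = 8L)
    lag1 <- function(co) {
        a <- subjectVolume(co, 1)
        cor(as.vector(a[-1, , ]), as.vector(a[-12, , ]))
    }
    expect_lt(abs(lag1(generateCohort(base)$cohort)), 0.2)
    expect_gt(lag1(generateCohort(smooth)$cohort), 0.5)
})
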