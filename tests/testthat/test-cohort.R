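test_that("VoxelGrid validates geometry and maps voxel/world coordinates", {
    expect_error(VoxelGrid(c(0, 4, 4)), "positive")
    expect_error(VoxelGrid(c(4, 4, 4), voxelSize = 0), "positive")
    expect_error(VoxelGrid(c(4, 4, 4), affine = matrix(0, 4, 4)),
                 "invertible")

    g <- VoxelGrid(c(5L, 4L, 3L), c(1.5, 2, 2.5))
    ijk <- rbind(c(0, 0, 0), c(4, 3, 2), c(2, 1.5, 1))
    expect_equal(voxelCoords(g, worldCoords(g, ijk)), ijk)
    # default origin centres the grid at world zero
    expect_equal(as.numeric(worldCoords(g, rbind((c(5, 4, 3) - 1) / 2))),
                 c(0, 0, 0))
})

test_that("annualize divides by the interval and is linear", {
    f <- array(-0.05, c(2, 2, 2))
    expect_equal(annualize(f, 1.0), f)
    expect_equal(annualize(f, 0.5), f / 0.5)
    expect_equal(as.numeric(annualize(c(-0.05, -0.02), 0.5)),
                 c(-0.10, -0.04))
    expect_error(annualize(f, 0), "> 0")
    # linearity: annualize(c * x, t) = c * annualize(x, t)
    x <- array(rnorm(8), c(2, 2, 2))
    expect_equal(annualize(3 * x, 0.7), 3 * annualize(x, 0.7))

    co <- tinyCohort(matrix(c(-0.06, -0.06, -0.02, -0.02), 2, 2),
                     groups = c("HC", "PAT"), intervals = c(2, 0.5))
    co2 <- annualize(co)
    expect_equal(unname(rateMatrix(co2)[, 1]), c(-0.03, -0.03))
    expect_equal(unname(rateMatrix(co2)[, 2]), c(-0.04, -0.04))
})

test_that("gray-matter masking multiplies values and defines the analysis mask", {
    grid <- tinyGrid(c(2L, 2L, 1L))
    co <- tinyCohort(matrix(-0.04, 4, 3), groups = c("HC", "HC", "PAT"),
                     grid = grid)
    gm1 <- GrayMatterMap(grid, array(1, c(2, 2, 1)))
    m1 <- applyGMMask(co, gm1)
    expect_equal(rateMatrix(m1), rateMatrix(co))      # identity on values
    expect_true(all(analysisMask(m1)))

    gm0 <- GrayMatterMap(grid, array(0, c(2, 2, 1)))
    m0 <- applyGMMask(co, gm0)
    expect_true(all(rateMatrix(m0) == 0))
    expect_false(any(analysisMask(m0)))
    expect_error(welchTMap(m0, "PAT"), "2 subjects")  # degenerate downstream

    p <- array(c(0.5, 1, 1, 1), c(2, 2, 1))
    mp <- applyGMMask(co, GrayMatterMap(grid, p), inclusionThreshold = 0.6)
    expect_equal(unname(rateMatrix(mp)[1, 1]), -0.02) # 0.5 * -0.04
    expect_equal(sum(analysisMask(mp)), 3L)

    badGrid <- VoxelGrid(c(2L, 2L, 2L), 1.5)
    expect_error(
        applyGMMask(co, GrayMatterMap(badGrid, array(1, c(2, 2, 2)))),
        "grid")
})

test_that("cohort container enforces unique ids and positive intervals", {
    vals <- matrix(0, 8, 2)
    grid <- tinyGrid(c(2L, 2L, 2L))
    expect_error(
        RateMapCohort(vals, grid, c("a", "a"), c("HC", "HC")),
        "unique")
    expect_error(
        RateMapCohort(vals, grid, c("a", "b"), c("HC", "HC"),
                      intervalYears = c(1, 0)),
        "positive")
})

test_that("NIfTI volumes round-trip bit-exactly with grid metadata", {
    grid <- VoxelGrid(c(6L, 5L, 4L), c(1.5, 1.5, 2))
    vals <- array(rnorm(120), c(6, 5, 4))
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeVolume(vals, grid, f, "double")
    back <- readVolume(f)
    expect_identical(as.numeric(back$values), as.numeric(vals))
    expect_equal(back$grid@shape, grid@shape)
    expect_equal(back$grid@affine, grid@affine, tolerance = 1e-5)
    expect_equal(back$grid@voxelSize, grid@voxelSize, tolerance = 1e-5)
})

test_that("cohorts round-trip through manifest + volumes", {
    dir <- withr::local_tempdir()
    spec <- smallSignalSpec(seed = 3L, nPerGroup = 3L)
    g <- generateCohort(spec, dir = dir)
    man <- file.path(dir, "manifest.csv")
    expect_true(file.exists(man))
    back <- readCohort(man, annualizeMaps = FALSE)
    expect_identical(unname(rateMatrix(back)),
                     unname(rateMatrix(g$cohort)))
    expect_equal(subjectIds(back), subjectIds(g$cohort))
    expect_equal(groups(back), groups(g$cohort))

    # annualization on load divides by the manifest interval
    m <- read.csv(man)
    m$interval_years <- 2
    write.csv(m, man, row.names = FALSE)
    halved <- readCohort(man, annualizeMaps = TRUE)
    expect_equal(unname(rateMatrix(halved)),
                 unname(rateMatrix(g$cohort)) / 2)
})

test_that("manifest validation rejects duplicates, bad intervals, bad grids", {
    dir <- withr::local_tempdir()
    grid <- tinyGrid(c(3L, 3L, 3L))
    for (i in 1:2)
        writeVolume(array(0, c(3, 3, 3)), grid,
                    file.path(dir, paste0("v", i, ".nii.gz")))
    man <- file.path(dir, "manifest.csv")
    base <- data.frame(subject_id = c("a", "b"), group = "HC",
                       interval_years = 1,
                       path = c("v1.nii.gz", "v2.nii.gz"))

    dup <- base; dup$subject_id <- c("a", "a")
    write.csv(dup, man, row.names = FALSE)
    expect_error(readCohort(man), "duplicate")

    bad <- base; bad$interval_years <- c(1, -1)
    write.csv(bad, man, row.names = FALSE)
    expect_error(readCohort(man), "positive")

    gone <- base; gone$path[2] <- "nope.nii.gz"
    write.csv(gone, man, row.names = FALSE)
    expect_error(readCohort(man), "missing")

    writeVolume(array(0, c(4, 4, 4)), tinyGrid(c(4L, 4L, 4L)),
                file.path(dir, "v2.nii.gz"))
    write.csv(base, man, row.names = FALSE)
    expect_error(readCohort(man), "grid mismatch")

    expect_error(readCohort(file.path(dir, "absent.csv")), "not found")
})

test_that("manifest group counts are preserved at cohort scale", {
    dir <- withr::local_tempdir()
    grid <- VoxelGrid(c(2L, 2L, 2L), 1.5)
    n <- c(HC = 97L, bvFTD = 44L)
    ids <- sprintf("s%03d", seq_len(sum(n)))
    writeVolume(array(0, c(2, 2, 2)), grid, file.path(dir, "flat.nii.gz"))
    man <- data.frame(subject_id = ids,
                      group = rep(names(n), n),
                      interval_years = 1, path = "flat.nii.gz")
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
    co <- readCohort(file.path(dir, "manifest.csv"))
    expect_equal(as.vector(table(groups(co))[names(n)]), unname(as.vector(n)))
    expect_equal(ncol(co), 141L)
})
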