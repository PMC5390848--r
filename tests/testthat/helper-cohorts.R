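# Small in-memory fixtures shared across the suite.

tinyGrid <- function(shape = c(4L, 4L, 4L), voxelSize = 1.5) {
    VoxelGrid(shape, voxelSize)
}

# Cohort from explicit per-subject flattened values (voxels x subjects).
tinyCohort <- function(values, groups, grid = NULL, intervals = 1) {
    values <- as.matrix(values)
    if (is.null(grid)) {
        n <- nrow(values)
        grid <- VoxelGrid(c(n, 1L, 1L), 1.5)
    }
    RateMapCohort(values, grid,
                  subjectId = sprintf("s%02d", seq_len(ncol(values))),
                  group = groups, intervalYears = intervals)
}

# A TStatResult built directly from a vector of t values (one voxel each),
# with patient means set to the sign of t so contraction-only filters pass
# for negative t.
tinyTStat <- function(tvals, meanPatients = NULL) {
    n <- length(tvals)
    grid <- VoxelGrid(c(n, 1L, 1L), 1.5)
    if (is.null(meanPatients)) meanPatients <- ifelse(tvals < 0, -1, 1)
    new("TStatResult", grid = grid, t = as.numeric(tvals),
        dof = rep(10, n), meanPatients = as.numeric(meanPatients),
        meanControls = rep(0, n), nPatients = 3L, nControls = 3L,
        mask = rep(TRUE, n))
}

# Independent brute-force Welch t / dof / pooled-d oracles (kept deliberately
# naive: direct transcription of the textbook formulas).
oracleWelch <- function(x, y) {
    nx <- length(x); ny <- length(y)
    vx <- sum((x - mean(x))^2) / (nx - 1)
    vy <- sum((y - mean(y))^2) / (ny - 1)
    se2 <- vx / nx + vy / ny
    list(t = (mean(x) - mean(y)) / sqrt(se2),
         dof = se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)))
}

oracleCohenD <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
    (mean(x) - mean(y)) / sp
}

# Small synthetic spec used where module tests need a planted signal fast.
smallSignalSpec <- function(seed = 11L, jitter = 0, nPerGroup = 20L,
                            meanRate = -0.03) {
    SyntheticSpec(grid = VoxelGrid(c(16L, 16L, 16L), 1.5),
                  nControls = nPerGroup, nPatients = nPerGroup,
                  foci = list(AtrophyFocus(c(0, 0, 0), 5, meanRate, 0.01)),
                  jitterSdMm = jitter, voxelNoiseSd = 0.003,
                  subjectDriftSd = 0.005, heterogeneityFwhmMm = 3,
                  patientGroup = "PAT", seed = seed)
}
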