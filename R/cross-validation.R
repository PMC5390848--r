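## Stratified repeated partitioning, per-partition ROI optimization, unbiased
## test-set effect sizes, and the effect-size-weighted consensus map.

#' Partition specification
#'
#' @param testFraction fraction of the cohort assigned to the test set
#'   (default 0.16; the test-set size is the nearest integer).
#' @param patientFractionBounds exclusive lower/upper bounds on the patient
#'   share of the test set (default 1/3 and 2/3).
#' @param nIterations number of random partitions (default 1024).
#' @param seed master RNG seed; every iteration derives its own substream so
#'   results are reproducible regardless of execution order.
#' @return validated list.
#' @export
partitionSpec <- function(testFraction = 0.16,
                          patientFractionBounds = c(1 / 3, 2 / 3),
                          nIterations = 1024L, seed = 1L) {
    stopifnot(testFraction > 0, testFraction < 1,
              length(patientFractionBounds) == 2L,
              patientFractionBounds[1] < patientFractionBounds[2],
              nIterations >= 1)
    list(testFraction = testFraction,
         patientFractionBounds = as.numeric(patientFractionBounds),
         nIterations = as.integer(nIterations), seed = as.integer(seed))
}

#' Admissible patient counts for a stratified test set
#'
#' @param nControls,nPatients group sizes.
#' @param spec a \code{\link{partitionSpec}}.
#' @return list(testSize, admissible) where admissible is the vector of
#'   patient counts m with bounds[1] * testSize < m < bounds[2] * testSize
#'   (strict) that are also feasible given the group sizes.
#' @export
admissiblePatientCounts <- function(nControls, nPatients,
                                    spec = partitionSpec()) {
    total <- nControls + nPatients
    testSize <- as.integer(round(spec$testFraction * total))
    b <- spec$patientFractionBounds
    lo <- floor(b[1] * testSize) + 1L
    hi <- ceiling(b[2] * testSize) - 1L
    m <- seq.int(max(lo, max(1L, testSize - nControls)),
                 min(hi, nPatients, testSize - 1L))
    m <- m[m >= lo & m <= hi]
    list(testSize = testSize, admissible = m)
}

#' One stratified train/test partition
#'
#' The test set holds round(testFraction x total) subjects; its patient count
#' is drawn uniformly from the admissible range, then members are sampled
#' without replacement within each group. Uses the current RNG state.
#'
#' @inheritParams admissiblePatientCounts
#' @return list(testControls, testPatients, trainControls, trainPatients) of
#'   within-group indices.
#' @export
stratifiedPartition <- function(nControls, nPatients,
                                spec = partitionSpec()) {
    adm <- admissiblePatientCounts(nControls, nPatients, spec)
    if (length(adm$admissible) == 0L)
        stop("no admissible test-set patient count for ", nControls,
             " controls + ", nPatients, " patients")
    m <- adm$admissible[sample.int(length(adm$admissible), 1L)]
    tp <- sort(sample.int(nPatients, m))
    tc <- sort(sample.int(nControls, adm$testSize - m))
    list(testControls = tc, testPatients = tp,
         trainControls = setdiff(seq_len(nControls), tc),
         trainPatients = setdiff(seq_len(nPatients), tp))
}

#' Effect-size-weighted consensus ROI
#'
#' Each voxel's weight is the proportion of cross-validation partitions whose
#' optimal ROI contains it, with every partition weighted by the magnitude of
#' its test-set effect size: w(v) = sum_k |d_k| 1[v in ROI_k] / sum_k |d_k|.
#' When every |d_k| is zero the unweighted proportion is used (with a
#' message).
#'
#' @param roiMasks list of logical 3-D arrays (one per partition).
#' @param testD numeric vector of the partitions' test-set effect sizes.
#' @param grid the \linkS4class{VoxelGrid}.
#' @return A \linkS4class{ConsensusMap}.
#' @export
consensusROI <- function(roiMasks, testD, grid) {
    stopifnot(length(roiMasks) == length(testD), length(roiMasks) >= 1L)
    w <- abs(testD)
    if (sum(w) == 0) {
        message("all test effect sizes are zero; using unweighted proportion")
        w <- rep(1, length(testD))
    }
    acc <- 0
    for (k in seq_along(roiMasks))
        acc <- acc + w[k] * as.numeric(roiMasks[[k]])
    new("ConsensusMap", grid = grid,
        weights = array(pmin(1, acc / sum(w)), dim = grid@shape))
}

#' Cross-validated ROI optimization
#'
#' Repeats, for \code{nIterations} stratified partitions: fit the voxelwise
#' Welch t map on the training subjects only, sweep thresholds, select the
#' smoothed-maximum ROI, then apply that fixed ROI to the held-out test
#' subjects to obtain an unbiased Cohen's d. Iterations where no voxel
#' reaches the starting threshold are recorded as failures and excluded from
#' the summary. The mean test d, its normal-theory 95 percent CI
#' (mean +/- 1.96 sd / sqrt(k)) and the effect-size-weighted consensus map
#' are returned.
#'
#' All randomness derives from \code{spec$seed} via per-iteration substreams,
#' so two runs with the same seed are bit-identical.
#'
#' @param cohort a masked \linkS4class{RateMapCohort} (see
#'   \code{\link{applyGMMask}}).
#' @param patients,controls group labels.
#' @param config a \code{\link{sweepConfig}}.
#' @param smoothing a \code{\link{smoothingConfig}}.
#' @param spec a \code{\link{partitionSpec}}.
#' @return A \linkS4class{CVResult}.
#' @export
runCV <- function(cohort, patients, controls = "HC",
                  config = sweepConfig(), smoothing = smoothingConfig(),
                  spec = partitionSpec()) {
    grp <- groups(cohort)
    ip <- which(grp == patients); ic <- which(grp == controls)
    nP <- length(ip); nC <- length(ic)
    if (nP < 2L || nC < 2L) stop("need at least 2 subjects per group")
    grid <- voxelGrid(cohort)

    set.seed(spec$seed)
    iterSeeds <- sample.int(.Machine$integer.max, spec$nIterations)

    recs <- vector("list", spec$nIterations)
    masks <- vector("list", spec$nIterations)
    for (i in seq_len(spec$nIterations)) {
        set.seed(iterSeeds[i])
        part <- stratifiedPartition(nC, nP, spec)
        trainCols <- c(ic[part$trainControls], ip[part$trainPatients])
        testCols <- c(ic[part$testControls], ip[part$testPatients])
        train <- cohort[, trainCols]
        test <- cohort[, testCols]
        rec <- data.frame(iteration = i, threshold = NA_real_,
                          n_voxels = NA_integer_, train_d = NA_real_,
                          test_d = NA_real_,
                          n_test_patients = length(part$testPatients),
                          ok = FALSE)
        roi <- tryCatch({
            ts <- welchTMap(train, patients, controls)
            optimizeTrainingROI(ts, train, patients, controls,
                                config, smoothing)
        }, noROIError = function(e) NULL)
        if (!is.null(roi)) {
            rec$threshold <- roi@threshold
            rec$n_voxels <- roi@nVoxels
            rec$train_d <- roi@trainingD
            rec$test_d <- cohensD(roi@mask, test, patients, controls)
            rec$ok <- TRUE
            masks[[i]] <- roi@mask
        }
        recs[[i]] <- rec
    }
    iterations <- do.call(rbind, recs)
    ok <- iterations$ok
    if (!any(ok))
        stop("all ", spec$nIterations, " iterations failed to form an ROI; ",
             "no voxel reached the starting threshold ", config$tStart)
    td <- iterations$test_d[ok]
    k <- length(td)
    meanD <- mean(td)
    half <- if (k > 1) 1.96 * sd(td) / sqrt(k) else 0
    consensus <- consensusROI(masks[ok], td, grid)
    # consensus weights are zero outside the analysis mask by construction
    new("CVResult", meanTestD = meanD, ci95 = c(meanD - half, meanD + half),
        iterations = iterations, nFailures = as.integer(sum(!ok)),
        consensus = consensus)
}
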