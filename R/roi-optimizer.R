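## Threshold sweep over the Welch t map, Cohen's d per candidate ROI, and the
## lowess / iterative-exclusion / median heuristic that picks the threshold
## maximizing the training-set effect size.

#' Sweep configuration
#'
#' @param tStart first t cutoff of the sweep (default 3.5).
#' @param tStep cutoff increment (default 0.01).
#' @param contractionOnly restrict candidate voxels to those where the
#'   patient mean rate is negative (default TRUE); expanding voxels are
#'   excluded because they would mostly reflect residual CSF.
#' @param minRoiVoxels smallest ROI admitted to the curve (default 10;
#'   set 1 for the strictest behaviour).
#' @return list with class validated fields.
#' @export
sweepConfig <- function(tStart = 3.5, tStep = 0.01, contractionOnly = TRUE,
                        minRoiVoxels = 10L) {
    stopifnot(tStart > 0, tStep > 0, minRoiVoxels >= 1)
    list(tStart = tStart, tStep = tStep,
         contractionOnly = isTRUE(contractionOnly),
         minRoiVoxels = as.integer(minRoiVoxels))
}

#' Smoothed-maximum configuration
#'
#' @param lowessSpan lowess smoother span as a fraction of curve points
#'   (default 0.3).
#' @param maxExclusionFraction largest fraction of the highest-t voxels
#'   excluded during the iterative truncation (default 0.10).
#' @param lowessIter lowess robustness iterations (default 1).
#' @return validated list.
#' @export
smoothingConfig <- function(lowessSpan = 0.3, maxExclusionFraction = 0.10,
                            lowessIter = 1L) {
    stopifnot(lowessSpan > 0, lowessSpan <= 1,
              maxExclusionFraction >= 0, maxExclusionFraction <= 0.5)
    list(lowessSpan = lowessSpan,
         maxExclusionFraction = maxExclusionFraction,
         lowessIter = as.integer(lowessIter))
}

.noRoi <- function(msg) {
    stop(structure(class = c("noROIError", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

## Contraction-direction magnitude: |t| for voxels on the contraction side
## (t < 0, optionally patient mean < 0), -Inf elsewhere.
.contractionMagnitude <- function(tstat, config) {
    m <- rep(-Inf, length(tstat@t))
    if (config$contractionOnly) {
        ok <- tstat@mask & !is.na(tstat@t) & tstat@t < 0 &
              tstat@meanPatients < 0
    } else {
        ok <- tstat@mask & !is.na(tstat@t)
    }
    m[ok] <- abs(tstat@t[ok])
    m
}

#' ROI at a single t threshold
#'
#' The ROI is the set of mask voxels whose contraction-direction |t| reaches
#' the threshold; with \code{contractionOnly} (the default) the patient mean
#' rate must also be negative.
#'
#' @param tstat a \linkS4class{TStatResult}.
#' @param threshold t cutoff (>= \code{config$tStart}).
#' @param config a \code{\link{sweepConfig}}.
#' @return logical 3-D array; errors with class \code{noROIError} when fewer
#'   than \code{minRoiVoxels} voxels survive.
#' @export
roiAtThreshold <- function(tstat, threshold, config = sweepConfig()) {
    if (threshold < config$tStart)
        stop("threshold must be >= tStart (", config$tStart, ")")
    m <- .contractionMagnitude(tstat, config)
    sel <- m >= threshold
    if (sum(sel) < config$minRoiVoxels)
        .noRoi(sprintf("no ROI at threshold %.2f (%d voxel(s) survive)",
                       threshold, sum(sel)))
    array(sel, dim = tstat@grid@shape)
}

## Pooled-SD Cohen's d from per-subject scalars.
.pooledD <- function(sp, sc) {
    np <- length(sp); nc <- length(sc)
    spool <- sqrt(((np - 1) * var(sp) + (nc - 1) * var(sc)) / (np + nc - 2))
    if (spool == 0) stop("zero pooled SD; Cohen's d undefined")
    (mean(sp) - mean(sc)) / spool
}

#' Cohen's d of ROI-mean annual change
#'
#' Each subject is reduced to the mean rate over the ROI voxels; d is the
#' patient-minus-control mean difference divided by the classic df-weighted
#' pooled SD. Negative d means patients contract faster.
#'
#' @param roi logical 3-D array (or flattened vector) selecting ROI voxels.
#' @param cohort a \linkS4class{RateMapCohort}.
#' @param patients,controls group labels.
#' @return signed Cohen's d.
#' @export
cohensD <- function(roi, cohort, patients, controls = "HC") {
    roi <- .flattenMask(roi, voxelGrid(cohort))
    if (!any(roi)) stop("ROI is empty")
    grp <- groups(cohort)
    ip <- which(grp == patients); ic <- which(grp == controls)
    if (length(ip) < 2L || length(ic) < 2L)
        stop("need at least 2 subjects per group")
    rates <- rateMatrix(cohort)[roi, , drop = FALSE]
    scal <- colMeans(rates)
    .pooledD(scal[ip], scal[ic])
}

#' Effect-size-versus-threshold sweep
#'
#' Forms the ROI at every cutoff from \code{tStart} to the maximum observed
#' contraction-direction |t| in steps of \code{tStep} and records its
#' Cohen's d and voxel count, skipping cutoffs whose ROI falls below
#' \code{minRoiVoxels}. Implemented with prefix sums over voxels sorted by
#' |t|, so the full sweep costs one pass over the candidate voxels.
#'
#' @inheritParams roiAtThreshold
#' @param cohort,patients,controls as in \code{\link{cohensD}}; the cohort
#'   must be the same set of subjects the t map was computed from.
#' @return An \linkS4class{EffectSizeCurve}; errors with class
#'   \code{noROIError} when no voxel reaches \code{tStart}.
#' @export
effectSizeSweep <- function(tstat, cohort, patients, controls = "HC",
                            config = sweepConfig()) {
    m <- .contractionMagnitude(tstat, config)
    cand <- which(m >= config$tStart)
    if (length(cand) < config$minRoiVoxels)
        .noRoi(sprintf(
            "no informative voxels: %d reach t = %.2f (need %d)",
            length(cand), config$tStart, config$minRoiVoxels))

    ord <- cand[order(m[cand], decreasing = TRUE)]
    mag <- m[ord]
    thresholds <- seq(config$tStart, mag[1], by = config$tStep)
    # ROI size at each cutoff: number of candidates with |t| >= cutoff
    magAsc <- rev(mag)
    counts <- length(mag) -
        findInterval(thresholds, magAsc, left.open = TRUE)

    grp <- groups(cohort)
    ip <- which(grp == patients); ic <- which(grp == controls)
    if (length(ip) < 2L || length(ic) < 2L)
        stop("need at least 2 subjects per group")
    rates <- rateMatrix(cohort)[ord, , drop = FALSE]
    cums <- apply(rates, 2L, cumsum)
    if (is.null(dim(cums))) cums <- matrix(cums, nrow = 1L)

    keep <- counts >= config$minRoiVoxels
    ks <- unique(counts[keep])
    dByK <- vapply(ks, function(k)
        .pooledD(cums[k, ip] / k, cums[k, ic] / k), numeric(1))
    d <- dByK[match(counts[keep], ks)]

    new("EffectSizeCurve", thresholds = thresholds[keep],
        effectSizes = d, voxelCounts = as.integer(counts[keep]))
}

#' Smoothed-maximum threshold selection
#'
#' At high cutoffs only a handful of voxels form the ROI, making the raw
#' maximum of the effect-size curve unstable. The heuristic repeatedly
#' truncates the high-threshold end of the curve -- excluding from 0 up to
#' \code{maxExclusionFraction} of the highest-|t| candidate voxels, stepping
#' the exclusion along the sweep grid -- lowess-smooths |d| against threshold
#' on each truncated curve, records the threshold of the smoothed maximum,
#' and returns the median of the recorded thresholds (ties and even-length
#' medians resolve to the lower threshold). Curves with fewer than 5 points
#' fall back to the raw argmax of |d|.
#'
#' @param curve an \linkS4class{EffectSizeCurve}.
#' @param smoothing a \code{\link{smoothingConfig}}.
#' @return the selected threshold (one of the curve's grid values).
#' @export
smoothedMaximum <- function(curve, smoothing = smoothingConfig()) {
    th <- curve@thresholds
    absd <- abs(curve@effectSizes)
    n <- length(th)
    if (n < 5L)
        return(th[which.max(absd)])

    counts <- curve@voxelCounts
    v0 <- counts[1]
    # one truncation per grid point in the top tail holding <= maxExclusion
    # of the candidate voxels, plus the untruncated curve
    tailIdx <- which(counts <= smoothing$maxExclusionFraction * v0)
    picks <- numeric(0)
    smoothPick <- function(idx) {
        if (length(idx) < 2L) return(th[idx][which.max(absd[idx])])
        lo <- lowess(th[idx], absd[idx], f = smoothing$lowessSpan,
                     iter = smoothing$lowessIter)
        # ties (to numerical tolerance) resolve to the lower threshold
        lo$x[which(lo$y >= max(lo$y) - 1e-10)[1]]
    }
    picks <- c(picks, smoothPick(seq_len(n)))
    for (j in tailIdx) {
        keepIdx <- which(counts > counts[j])
        if (length(keepIdx) == 0L) keepIdx <- 1L
        picks <- c(picks, smoothPick(keepIdx))
    }
    # lower median keeps the result on the sweep grid
    sorted <- sort(picks)
    sorted[floor((length(sorted) + 1) / 2)]
}

#' Optimize the training-set ROI
#'
#' Composition of \code{\link{effectSizeSweep}},
#' \code{\link{smoothedMaximum}} and \code{\link{roiAtThreshold}}: selects
#' the t cutoff whose ROI maximizes the (smoothed) training effect size and
#' returns that ROI with its training Cohen's d.
#'
#' @inheritParams effectSizeSweep
#' @param smoothing a \code{\link{smoothingConfig}}.
#' @return An \linkS4class{OptimalROI}.
#' @export
optimizeTrainingROI <- function(tstat, cohort, patients, controls = "HC",
                                config = sweepConfig(),
                                smoothing = smoothingConfig()) {
    curve <- effectSizeSweep(tstat, cohort, patients, controls, config)
    thr <- smoothedMaximum(curve, smoothing)
    mask <- roiAtThreshold(tstat, thr, config)
    i <- match(thr, curve@thresholds)
    d <- if (is.na(i)) cohensD(mask, cohort, patients, controls)
         else curve@effectSizes[i]
    new("OptimalROI", threshold = thr, mask = mask, trainingD = d,
        nVoxels = as.integer(sum(mask)))
}
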