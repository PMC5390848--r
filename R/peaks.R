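## Per-subject peak-atrophy localization and the cross-subject dispersion of
## peak locations: the spatial-heterogeneity readout that tracks (inversely)
## with the achievable data-driven effect size.

## Neighborhood mean within radiusMm of every voxel (brute-force shift-and-
## average over the offset stencil; offsets leaving the grid are dropped per
## voxel so edge voxels average over their available neighbours).
.neighborhoodMean <- function(arr, grid, radiusMm) {
    off <- as.matrix(expand.grid(
        i = -floor(radiusMm / grid@voxelSize[1]):floor(radiusMm / grid@voxelSize[1]),
        j = -floor(radiusMm / grid@voxelSize[2]):floor(radiusMm / grid@voxelSize[2]),
        k = -floor(radiusMm / grid@voxelSize[3]):floor(radiusMm / grid@voxelSize[3])))
    dist <- sqrt((off[, 1] * grid@voxelSize[1])^2 +
                 (off[, 2] * grid@voxelSize[2])^2 +
                 (off[, 3] * grid@voxelSize[3])^2)
    off <- off[dist <= radiusMm, , drop = FALSE]
    d <- dim(arr)
    acc <- array(0, d); cnt <- array(0, d)
    for (r in seq_len(nrow(off))) {
        oi <- off[r, 1]; oj <- off[r, 2]; ok <- off[r, 3]
        si <- max(1, 1 - oi):min(d[1], d[1] - oi)
        sj <- max(1, 1 - oj):min(d[2], d[2] - oj)
        sk <- max(1, 1 - ok):min(d[3], d[3] - ok)
        acc[si, sj, sk] <- acc[si, sj, sk] +
            arr[si + oi, sj + oj, sk + ok]
        cnt[si, sj, sk] <- cnt[si, sj, sk] + 1
    }
    acc / cnt
}

#' Per-subject peak-atrophy locations
#'
#' For every subject, finds the voxel with the most negative (optionally
#' neighborhood-averaged) annual change inside the mask -- the location of
#' fastest contraction. Ties resolve to the lowest linear voxel index.
#'
#' @param cohort a \linkS4class{RateMapCohort}.
#' @param mask logical mask (3-D array or flattened); defaults to the
#'   cohort's analysis mask.
#' @param neighborhoodRadiusMm radius of a spherical averaging neighborhood
#'   in mm; 0 (the default) uses raw voxel values.
#' @return data.frame with columns subject_id, group, i, j, k (0-based voxel
#'   indices), x, y, z (world mm) and value (1/year at the peak).
#' @export
peakLocations <- function(cohort, mask = NULL, neighborhoodRadiusMm = 0) {
    grid <- voxelGrid(cohort)
    if (is.null(mask)) mask <- analysisMask(cohort)
    if (is.null(mask)) mask <- rep(TRUE, prod(grid@shape))
    mask <- .flattenMask(mask, grid)
    if (!any(mask)) stop("mask is empty")
    rates <- rateMatrix(cohort)
    n <- ncol(rates)
    out <- data.frame(subject_id = subjectIds(cohort),
                      group = groups(cohort),
                      i = integer(n), j = integer(n), k = integer(n),
                      x = numeric(n), y = numeric(n), z = numeric(n),
                      value = numeric(n))
    for (s in seq_len(n)) {
        v <- rates[, s]
        if (neighborhoodRadiusMm > 0)
            v <- as.vector(.neighborhoodMean(
                array(v, dim = grid@shape), grid, neighborhoodRadiusMm))
        v[!mask] <- Inf
        lin <- which.min(v)   # first minimum = lowest linear index
        ijk <- arrayInd(lin, grid@shape) - 1L
        xyz <- worldCoords(grid, ijk)
        out$i[s] <- ijk[1]; out$j[s] <- ijk[2]; out$k[s] <- ijk[3]
        out$x[s] <- xyz[1]; out$y[s] <- xyz[2]; out$z[s] <- xyz[3]
        out$value[s] <- v[lin]
    }
    out
}

#' Cross-subject peak dispersion
#'
#' Mean pairwise Euclidean distance (mm) between per-subject peak locations:
#' small when peaks cluster tightly across subjects, large when the fastest-
#' atrophying location varies between individuals.
#'
#' @param peaks output of \code{\link{peakLocations}} (or any data.frame /
#'   matrix with x, y, z columns), at least 2 rows.
#' @return mean pairwise distance in mm.
#' @export
peakDispersion <- function(peaks) {
    coords <- if (is.data.frame(peaks)) as.matrix(peaks[, c("x", "y", "z")])
              else as.matrix(peaks)
    if (nrow(coords) < 2L) stop("need at least 2 peaks")
    mean(dist(coords))
}

#' Peak-count overlay volume
#'
#' @param peaks output of \code{\link{peakLocations}}.
#' @param grid the \linkS4class{VoxelGrid}.
#' @return integer 3-D array counting peaks per voxel (writable as NIfTI).
#' @export
peakCountMap <- function(peaks, grid) {
    cnt <- array(0L, dim = grid@shape)
    for (r in seq_len(nrow(peaks))) {
        idx <- cbind(peaks$i[r], peaks$j[r], peaks$k[r]) + 1L
        cnt[idx] <- cnt[idx] + 1L
    }
    cnt
}
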