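## Voxelwise two-group Welch statistics over the analysis mask.

## Core Welch machinery on voxels x subjects matrices (rows may be any
## subset of voxels). Returns per-row t, Satterthwaite dof and group means.
.welchRows <- function(xp, xc) {
    np <- ncol(xp); nc <- ncol(xc)
    mp <- rowMeans(xp); mc <- rowMeans(xc)
    vp <- rowSums((xp - mp)^2) / (np - 1)
    vc <- rowSums((xc - mc)^2) / (nc - 1)
    a <- vp / np; b <- vc / nc
    se2 <- a + b
    t <- (mp - mc) / sqrt(se2)
    dof <- se2^2 / (a^2 / (np - 1) + b^2 / (nc - 1))
    list(t = t, dof = dof, meanP = mp, meanC = mc,
         defined = se2 > 0)
}

#' Voxelwise Welch t map (patients vs controls)
#'
#' Computes, at every voxel of the analysis mask, the two-sample t statistic
#' allowing unequal group variances, with Welch-Satterthwaite degrees of
#' freedom. Faster contraction (more negative change) in patients gives
#' negative t. Voxels where both group variances are zero have no defined t
#' and are removed from the result's mask (a message reports how many).
#'
#' @param cohort a \linkS4class{RateMapCohort}.
#' @param patients group label of the patient group.
#' @param controls group label of the control group (default "HC").
#' @param mask optional logical mask (3-D array or flattened); defaults to
#'   the cohort's analysis mask, or all voxels if none is set.
#' @return A \linkS4class{TStatResult}.
#' @export
welchTMap <- function(cohort, patients, controls = "HC", mask = NULL) {
    grp <- groups(cohort)
    ip <- which(grp == patients); ic <- which(grp == controls)
    if (length(ip) < 2L || length(ic) < 2L)
        stop("need at least 2 subjects per group (got ",
             length(ip), " vs ", length(ic), ")")
    grid <- voxelGrid(cohort)
    if (is.null(mask)) mask <- analysisMask(cohort)
    if (is.null(mask)) mask <- rep(TRUE, prod(grid@shape))
    mask <- .flattenMask(mask, grid)

    rates <- rateMatrix(cohort)
    idx <- which(mask)
    w <- .welchRows(rates[idx, ip, drop = FALSE],
                    rates[idx, ic, drop = FALSE])
    nUndef <- sum(!w$defined)
    if (nUndef > 0)
        message(nUndef,
            " voxel(s) with zero variance in both groups excluded from mask")

    nvox <- prod(grid@shape)
    t <- dof <- mp <- mc <- rep(NA_real_, nvox)
    keep <- idx[w$defined]
    t[keep] <- w$t[w$defined]
    dof[keep] <- w$dof[w$defined]
    mp[idx] <- w$meanP; mc[idx] <- w$meanC
    outMask <- rep(FALSE, nvox); outMask[keep] <- TRUE
    new("TStatResult", grid = grid, t = t, dof = dof,
        meanPatients = mp, meanControls = mc,
        nPatients = length(ip), nControls = length(ic), mask = outMask)
}

#' Export a TStatResult as NIfTI volumes
#'
#' @param tstat a \linkS4class{TStatResult}.
#' @param tPath,dofPath output paths (NA values outside the mask are written
#'   as 0).
#' @return invisibly, the paths written.
#' @export
writeTStat <- function(tstat, tPath, dofPath = NULL) {
    tv <- tstat@t; tv[is.na(tv)] <- 0
    writeVolume(tv, tstat@grid, tPath, "double")
    if (!is.null(dofPath)) {
        dv <- tstat@dof; dv[is.na(dv)] <- 0
        writeVolume(dv, tstat@grid, dofPath, "double")
    }
    invisible(c(tPath, dofPath))
}
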