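## Synthetic change-map cohorts with planted ground truth. Controls carry
## i.i.d. voxel noise around a drift mean; patients additionally lose volume
## inside spherical foci whose centres are rigidly translated per subject by
## a 3-D Gaussian jitter -- the knob for between-subject heterogeneity in
## atrophy location.

.gridWorld <- function(grid) {
    ijk <- as.matrix(expand.grid(i = seq_len(grid@shape[1]) - 1,
                                 j = seq_len(grid@shape[2]) - 1,
                                 k = seq_len(grid@shape[3]) - 1))
    worldCoords(grid, ijk)
}

#' Synthetic gray-matter probability map
#'
#' A smooth ellipsoidal "brain": probability 1 inside 70 percent of the
#' grid half-extent (normalized ellipsoidal radius), falling linearly to 0 at
#' 95 percent, so gray-matter masking is genuinely exercised.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param coreFrac,edgeFrac normalized radii of the p = 1 core and the p = 0
#'   edge.
#' @return A \linkS4class{GrayMatterMap}.
#' @export
syntheticGrayMatter <- function(grid, coreFrac = 0.7, edgeFrac = 0.95) {
    xyz <- .gridWorld(grid)
    half <- grid@voxelSize * (grid@shape - 1L) / 2
    ctr <- colMeans(worldCoords(grid, rbind(c(0, 0, 0), grid@shape - 1L)))
    rho <- sqrt(((xyz[, 1] - ctr[1]) / half[1])^2 +
                ((xyz[, 2] - ctr[2]) / half[2])^2 +
                ((xyz[, 3] - ctr[3]) / half[3])^2)
    p <- pmin(1, pmax(0, (edgeFrac - rho) / (edgeFrac - coreFrac)))
    GrayMatterMap(grid, array(p, dim = grid@shape))
}

## Per-voxel focus contribution profile at squared distance d2 from centre.
.focusProfile <- function(focus, d2) {
    r2 <- focus@radiusMm^2
    if (focus@profile == "uniform-sphere") {
        as.numeric(d2 <= r2)
    } else {
        # Gaussian falloff with sd = radius / 2, truncated at 2 radii
        w <- exp(-d2 / (2 * (focus@radiusMm / 2)^2))
        w[d2 > 4 * r2] <- 0
        w
    }
}

## Separable Gaussian smoothing along one axis (replicate-padded edges).
.smoothAxis <- function(arr, ax, sdVox) {
    d <- dim(arr)
    half <- max(1L, ceiling(3 * sdVox))
    k <- exp(-((-half:half)^2) / (2 * sdVox^2))
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = d[ax])
    pad <- rbind(m[rep(1L, half), , drop = FALSE], m,
                 m[rep(nrow(m), half), , drop = FALSE])
    sm <- stats::filter(pad, k, sides = 2)
    m <- matrix(sm[half + seq_len(d[ax]), ], nrow = d[ax])
    aperm(array(m, dim = d[perm]), order(perm))
}

## 3-D separable Gaussian smoothing of a flattened field.
.smooth3d <- function(v, grid, fwhmMm) {
    arr <- array(v, dim = grid@shape)
    for (ax in 1:3) {
        sdVox <- fwhmMm / 2.3548 / grid@voxelSize[ax]
        if (sdVox > 0) arr <- .smoothAxis(arr, ax, sdVox)
    }
    as.vector(arr)
}

## Unit-variance smooth random field (between-subject atrophy heterogeneity).
.heterogeneityField <- function(grid, fwhmMm) {
    f <- .smooth3d(rnorm(prod(grid@shape)), grid, fwhmMm)
    f / sd(f)
}

#' Generate a synthetic change-map cohort
#'
#' Draws a cohort under the generative model in \linkS4class{SyntheticSpec}:
#' every subject receives a whole-map rate offset (mean
#' \code{controlDriftMean}, SD \code{subjectDriftSd}) plus i.i.d. voxel
#' noise; patients additionally receive, inside each focus (rigidly
#' translated by the subject's jitter), the focus mean rate plus a
#' per-subject smooth heterogeneity field (unit-variance Gaussian random
#' field of FWHM \code{heterogeneityFwhmMm}, scaled by the focus
#' between-subject SD), everything weighted by the focus profile. Returned
#' ground truth holds the per-subject realized focus centres, the planted
#' ROI mask (union of the nominal, unjittered foci) and the realized
#' effect sizes (Cohen's d of planted-mask / per-focus mean change, patients
#' vs controls, on the generated maps). An identical seed yields a
#' bit-identical cohort. Jittered foci are clipped to the grid with a
#' warning when a centre leaves it.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir optional output directory; when given, NIfTI volumes, a CSV
#'   manifest, the gray-matter map, the planted ROI and a JSON ground-truth
#'   sidecar are written there.
#' @return list(cohort = \linkS4class{RateMapCohort} (unmasked; apply
#'   \code{\link{applyGMMask}} before statistics), gm =
#'   \linkS4class{GrayMatterMap}, truth = list(realizedCenters, plantedMask,
#'   plantedEffectSize, focusEffectSizes)).
#' @export
generateCohort <- function(spec, dir = NULL) {
    grid <- spec@grid
    nvox <- prod(grid@shape)
    xyz <- .gridWorld(grid)
    lims <- apply(worldCoords(grid, rbind(c(0, 0, 0), grid@shape - 1L)),
                  2, range)
    gm <- syntheticGrayMatter(grid)

    nC <- spec@nControls; nP <- spec@nPatients
    ids <- c(sprintf("ctrl%03d", seq_len(nC)),
             sprintf("pat%03d", seq_len(nP)))
    grp <- c(rep("HC", nC), rep(spec@patientGroup, nP))
    rates <- matrix(0, nvox, nC + nP)
    realized <- vector("list", nP)

    set.seed(spec@seed)
    clipped <- FALSE
    for (s in seq_len(nC + nP)) {
        drift <- rnorm(1, spec@controlDriftMean, spec@subjectDriftSd)
        noise <- rnorm(nvox, 0, spec@voxelNoiseSd)
        if (spec@smoothFwhmMm > 0 && spec@voxelNoiseSd > 0)
            noise <- .smooth3d(noise, grid, spec@smoothFwhmMm)
        v <- drift + noise
        if (s > nC && length(spec@foci)) {
            shift <- rnorm(3, 0, spec@jitterSdMm)
            field <- .heterogeneityField(grid, spec@heterogeneityFwhmMm)
            centers <- matrix(NA_real_, length(spec@foci), 3)
            for (f in seq_along(spec@foci)) {
                focus <- spec@foci[[f]]
                ctr <- focus@center + shift
                if (any(ctr < lims[1, ]) || any(ctr > lims[2, ])) {
                    clipped <- TRUE
                    ctr <- pmin(pmax(ctr, lims[1, ]), lims[2, ])
                }
                centers[f, ] <- ctr
                d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
                      (xyz[, 3] - ctr[3])^2
                v <- v + (focus@meanRate +
                          focus@betweenSubjectSd * field) *
                     .focusProfile(focus, d2)
            }
            realized[[s - nC]] <- centers
        }
        rates[, s] <- v
    }
    if (clipped)
        warning("some jittered focus centres left the grid and were clipped")

    cohort <- RateMapCohort(rates, grid, ids, grp, intervalYears = 1)

    planted <- rep(FALSE, nvox)
    focusMasks <- vector("list", length(spec@foci))
    for (f in seq_along(spec@foci)) {
        focus <- spec@foci[[f]]
        d2 <- (xyz[, 1] - focus@center[1])^2 +
              (xyz[, 2] - focus@center[2])^2 +
              (xyz[, 3] - focus@center[3])^2
        focusMasks[[f]] <- .focusProfile(focus, d2) > 0.5
        planted <- planted | focusMasks[[f]]
    }
    dOf <- function(m) {
        if (!any(m) || !length(spec@foci)) return(NA_real_)
        # degenerate (noise-free) cohorts have zero pooled SD
        tryCatch(cohensD(m, cohort, spec@patientGroup, "HC"),
                 error = function(e) NA_real_)
    }
    truth <- list(
        realizedCenters = realized,
        plantedMask = array(planted, dim = grid@shape),
        plantedEffectSize = dOf(planted),
        focusEffectSizes = vapply(focusMasks, dOf, numeric(1)))

    if (!is.null(dir)) {
        writeCohort(cohort, dir)
        writeVolume(gm@probabilities, grid, file.path(dir, "gm.nii.gz"),
                    "double")
        writeVolume(truth$plantedMask, grid,
                    file.path(dir, "planted_roi.nii.gz"), "uint8")
        jsonlite::write_json(
            list(patient_group = spec@patientGroup,
                 seed = spec@seed,
                 jitter_sd_mm = spec@jitterSdMm,
                 planted_effect_size = truth$plantedEffectSize,
                 focus_effect_sizes = truth$focusEffectSizes,
                 realized_centers = lapply(realized, function(m)
                     if (is.null(m)) NULL else unname(as.data.frame(m)))),
            file.path(dir, "ground_truth.json"), digits = NA)
    }
    list(cohort = cohort, gm = gm, truth = truth)
}

#' Variant-like synthetic presets
#'
#' Three cohort presets mimicking the qualitative structure of the FTLD
#' clinical variants: "svPPA-like" has one compact focus with strong, tightly
#' clustered atrophy (small spatial jitter); "nfvPPA-like" is intermediate;
#' "bvFTD-like" has several dispersed foci, weaker and more heterogeneous
#' rates, and the largest jitter. Rate parameters were calibrated once
#' against the planted-mask effect size so the three presets span effect
#' sizes of the order of the published variant values (roughly -3, -1.9
#' and -1.4 at the planted mask), and the jitter ordering
#' svPPA < nfvPPA < bvFTD drives both the cross-validated effect-size
#' ordering and the peak-dispersion ordering.
#'
#' @param name one of "svPPA-like", "nfvPPA-like", "bvFTD-like".
#' @param nControls,nPatients group sizes (default 30 each, sized so the full
#'   cross-validation runs in minutes on a single CPU).
#' @param seed RNG seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
variantPreset <- function(name = c("svPPA-like", "nfvPPA-like", "bvFTD-like"),
                          nControls = 30L, nPatients = 30L, seed = 1L) {
    name <- match.arg(name)
    grid <- VoxelGrid(c(32L, 32L, 32L), 1.5)
    preset <- switch(name,
        "svPPA-like" = list(
            foci = list(AtrophyFocus(c(-4, -3, 0), 8, -0.030, 0.018)),
            jitter = 1, group = "svPPA"),
        "nfvPPA-like" = list(
            foci = list(AtrophyFocus(c(-6, 4, 2), 6.5, -0.026, 0.018),
                        AtrophyFocus(c(6, -4, -2), 6.5, -0.026, 0.018)),
            jitter = 2.5, group = "nfvPPA"),
        "bvFTD-like" = list(
            foci = list(AtrophyFocus(c(-9, -6, 0), 10, -0.018, 0.018),
                        AtrophyFocus(c(9, 5, -3), 10, -0.018, 0.018),
                        AtrophyFocus(c(0, 6, 8), 10, -0.018, 0.018)),
            jitter = 6, group = "bvFTD"))
    SyntheticSpec(grid = grid, nControls = nControls, nPatients = nPatients,
                  foci = preset$foci, jitterSdMm = preset$jitter,
                  voxelNoiseSd = 0.003, subjectDriftSd = 0.009,
                  heterogeneityFwhmMm = 3, patientGroup = preset$group,
                  seed = seed)
}
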