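#' @import methods
#' @importFrom stats dist lowess median pt qt rnorm sd var qnorm pnorm setNames
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay "assay<-" colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Voxel grid geometry
#'
#' Describes the common sampling grid shared by all volumes in an analysis:
#' array dimensions, voxel size in mm, and a 4x4 affine mapping 0-based voxel
#' indices (i, j, k, 1) to world coordinates in mm.
#'
#' @slot shape integer(3), array dimensions (all >= 1).
#' @slot voxelSize numeric(3), voxel edge lengths in mm (all > 0).
#' @slot affine 4x4 numeric matrix, voxel-to-world mapping; must be invertible.
#'
#' @export
setClass("VoxelGrid",
    representation(shape = "integer", voxelSize = "numeric", affine = "matrix"))

setValidity("VoxelGrid", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 1L))
        msg <- c(msg, "shape must be 3 positive integers")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "voxelSize must be 3 positive reals")
    if (!all(dim(object@affine) == c(4L, 4L)))
        msg <- c(msg, "affine must be 4x4")
    else if (abs(det(object@affine)) < .Machine$double.eps * 64)
        msg <- c(msg, "affine must be invertible")
    if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param shape integer(3) array dimensions.
#' @param voxelSize numeric(3) or scalar, voxel size in mm (default 1.5).
#' @param affine optional 4x4 voxel-to-world affine. The default is a diagonal
#'   scaling by \code{voxelSize} with the origin placed so that the grid
#'   centre sits at world (0, 0, 0).
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(c(32, 32, 32), 1.5)
#' worldCoords(g, rbind(c(15.5, 15.5, 15.5)))  # grid centre -> ~origin
#' @export
VoxelGrid <- function(shape, voxelSize = 1.5, affine = NULL) {
    shape <- as.integer(shape)
    voxelSize <- rep_len(as.numeric(voxelSize), 3L)
    if (is.null(affine)) {
        affine <- diag(c(voxelSize, 1))
        affine[1:3, 4] <- -voxelSize * (shape - 1L) / 2
    }
    new("VoxelGrid", shape = shape, voxelSize = voxelSize, affine = affine)
}

#' Map voxel indices to world coordinates
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param ijk numeric matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
worldCoords <- function(grid, ijk) {
    ijk <- matrix(as.numeric(ijk), ncol = 3L)
    h <- cbind(ijk, 1) %*% t(grid@affine)
    h[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#'
#' @inheritParams worldCoords
#' @param xyz numeric matrix (n x 3) of world coordinates in mm.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
voxelCoords <- function(grid, xyz) {
    xyz <- matrix(as.numeric(xyz), ncol = 3L)
    h <- cbind(xyz, 1) %*% t(solve(grid@affine))
    h[, 1:3, drop = FALSE]
}

setMethod("show", "VoxelGrid", function(object) {
    cat(sprintf("VoxelGrid %s at %s mm\n",
        paste(object@shape, collapse = "x"),
        paste(format(object@voxelSize), collapse = "x")))
})

#' Gray-matter probability map
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot probabilities 3-D array of tissue probabilities in [0, 1].
#' @export
setClass("GrayMatterMap",
    representation(grid = "VoxelGrid", probabilities = "array"))

setValidity("GrayMatterMap", function(object) {
    p <- object@probabilities
    if (!identical(dim(p), as.integer(object@grid@shape)))
        return("probabilities shape must equal grid shape")
    if (anyNA(p) || min(p) < 0 || max(p) > 1)
        return("probabilities must lie in [0, 1]")
    TRUE
})

#' @rdname GrayMatterMap-class
#' @param grid a \linkS4class{VoxelGrid}.
#' @param probabilities 3-D array in [0, 1] with dim equal to grid shape.
#' @export
GrayMatterMap <- function(grid, probabilities) {
    new("GrayMatterMap", grid = grid,
        probabilities = array(as.numeric(probabilities), dim = grid@shape))
}

#' Cohort of annualized volume-change maps
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"rate"} holds
#' one column per subject of flattened (column-major) annual relative
#' volume-change values (units 1/year; negative = tissue contraction).
#' Column data carry \code{subject_id}, \code{group} and
#' \code{interval_years}; the \linkS4class{VoxelGrid} and the logical
#' analysis mask live in \code{metadata()}.
#'
#' @export
setClass("RateMapCohort", contains = "SummarizedExperiment")

setValidity("RateMapCohort", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("subject_id", "group", "interval_years")
    if (!all(need %in% colnames(cd)))
        return(paste("colData must contain", paste(need, collapse = ", ")))
    if (anyDuplicated(cd$subject_id))
        msg <- c(msg, "subject ids must be unique")
    if (any(cd$interval_years <= 0))
        msg <- c(msg, "interscan intervals must be positive")
    g <- S4Vectors::metadata(object)$grid
    if (!is(g, "VoxelGrid"))
        msg <- c(msg, "metadata()$grid must be a VoxelGrid")
    else if (prod(g@shape) != nrow(object))
        msg <- c(msg, "assay rows must equal prod(grid shape)")
    if (length(msg)) msg else TRUE
})

#' Construct a RateMapCohort
#'
#' @param rates numeric matrix, voxels x subjects (column-major flattening of
#'   each subject's 3-D map), or a list of 3-D arrays.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param subjectId character vector of unique subject identifiers.
#' @param group character/factor group labels (e.g. "HC", "svPPA").
#' @param intervalYears positive interscan intervals in years. Use 1 when the
#'   maps are already annualized.
#' @param analysisMask optional logical 3-D array (or flattened vector)
#'   restricting downstream statistics.
#' @return A \linkS4class{RateMapCohort}.
#' @export
RateMapCohort <- function(rates, grid, subjectId, group,
                          intervalYears = 1, analysisMask = NULL) {
    if (is.list(rates))
        rates <- vapply(rates, as.vector, numeric(prod(grid@shape)))
    rates <- as.matrix(rates)
    colnames(rates) <- subjectId
    cd <- S4Vectors::DataFrame(
        subject_id = as.character(subjectId),
        group = as.character(group),
        interval_years = rep_len(as.numeric(intervalYears), ncol(rates)),
        row.names = subjectId)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(rate = rates), colData = cd,
        metadata = list(grid = grid,
                        analysisMask = .flattenMask(analysisMask, grid)))
    new("RateMapCohort", se)
}

.flattenMask <- function(mask, grid) {
    if (is.null(mask)) return(NULL)
    mask <- as.logical(mask)
    stopifnot(length(mask) == prod(grid@shape))
    mask
}

setMethod("show", "RateMapCohort", function(object) {
    g <- voxelGrid(object)
    tab <- table(groups(object))
    cat(sprintf("RateMapCohort: %d subjects (%s) on %s grid\n",
        ncol(object),
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        paste(g@shape, collapse = "x")))
    m <- analysisMask(object)
    if (!is.null(m))
        cat(sprintf("  analysis mask: %d voxels\n", sum(m)))
})

#' Voxelwise Welch t-statistic result
#'
#' Two-group (patients vs controls) Welch t statistics with per-voxel
#' Satterthwaite degrees of freedom, defined only inside the analysis mask.
#' Sign convention: faster contraction in patients gives negative t.
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot t numeric vector (flattened), NA outside the mask.
#' @slot dof per-voxel Welch-Satterthwaite degrees of freedom, NA outside.
#' @slot meanPatients,meanControls per-voxel group means.
#' @slot nPatients,nControls group sizes.
#' @slot mask logical vector; voxels where t is defined.
#' @export
setClass("TStatResult",
    representation(grid = "VoxelGrid", t = "numeric", dof = "numeric",
        meanPatients = "numeric", meanControls = "numeric",
        nPatients = "integer", nControls = "integer", mask = "logical"))

setMethod("show", "TStatResult", function(object) {
    tv <- object@t[object@mask]
    cat(sprintf(
        "TStatResult: %d vs %d subjects, %d voxels, t range [%.2f, %.2f]\n",
        object@nPatients, object@nControls, sum(object@mask),
        min(tv), max(tv)))
})

#' Effect size versus t-threshold curve
#'
#' One point per t-threshold of the sweep: the Cohen's d of the ROI formed at
#' that threshold and its voxel count. Thresholds are strictly increasing and
#' voxel counts non-increasing.
#'
#' @slot thresholds ascending t cutoffs.
#' @slot effectSizes Cohen's d (signed; negative = faster patient contraction).
#' @slot voxelCounts ROI sizes, non-increasing with threshold.
#' @export
setClass("EffectSizeCurve",
    representation(thresholds = "numeric", effectSizes = "numeric",
                   voxelCounts = "integer"))

setValidity("EffectSizeCurve", function(object) {
    n <- length(object@thresholds)
    if (length(object@effectSizes) != n || length(object@voxelCounts) != n)
        return("field lengths differ")
    if (n > 1 && any(diff(object@thresholds) <= 0))
        return("thresholds must be strictly increasing")
    if (n > 1 && any(diff(object@voxelCounts) > 0))
        return("voxel counts must be non-increasing in threshold")
    if (any(object@voxelCounts < 1L))
        return("voxel counts must be positive")
    TRUE
})

setMethod("show", "EffectSizeCurve", function(object) {
    i <- which.max(abs(object@effectSizes))
    cat(sprintf(
        "EffectSizeCurve: %d thresholds in [%.2f, %.2f]; peak |d| %.3f at t >= %.2f\n",
        length(object@thresholds), min(object@thresholds),
        max(object@thresholds), abs(object@effectSizes[i]),
        object@thresholds[i]))
})

#' @describeIn EffectSizeCurve-class coerce to a data.frame with columns
#'   threshold, d, n_voxels.
#' @param x an EffectSizeCurve.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "EffectSizeCurve", function(x, ...) {
    data.frame(threshold = x@thresholds, d = x@effectSizes,
               n_voxels = x@voxelCounts)
})

#' Optimal training-set ROI
#'
#' @slot threshold selected t cutoff.
#' @slot mask logical 3-D array of ROI membership.
#' @slot trainingD Cohen's d of the ROI on the training set.
#' @slot nVoxels ROI size.
#' @export
setClass("OptimalROI",
    representation(threshold = "numeric", mask = "array",
                   trainingD = "numeric", nVoxels = "integer"))

setValidity("OptimalROI", function(object) {
    if (object@nVoxels < 1L || !any(object@mask))
        return("ROI mask must be nonempty")
    TRUE
})

setMethod("show", "OptimalROI", function(object) {
    cat(sprintf("OptimalROI: t >= %.2f, %d voxels, training d = %.3f\n",
        object@threshold, object@nVoxels, object@trainingD))
})

#' Consensus ROI map
#'
#' Voxelwise weights in [0, 1]: the effect-size-weighted proportion of
#' cross-validation partitions whose optimal ROI contains the voxel.
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot weights 3-D array of weights in [0, 1]; 0 outside the analysis mask.
#' @export
setClass("ConsensusMap",
    representation(grid = "VoxelGrid", weights = "array"))

setValidity("ConsensusMap", function(object) {
    w <- object@weights
    if (!identical(dim(w), as.integer(object@grid@shape)))
        return("weights shape must equal grid shape")
    if (anyNA(w) || min(w) < 0 || max(w) > 1 + 1e-12)
        return("weights must lie in [0, 1]")
    TRUE
})

setMethod("show", "ConsensusMap", function(object) {
    cat(sprintf("ConsensusMap: %d voxels with weight > 0 (max %.3f)\n",
        sum(object@weights > 0), max(object@weights)))
})

#' Cross-validation summary
#'
#' @slot meanTestD mean held-out Cohen's d over successful iterations.
#' @slot ci95 normal-theory 95 percent confidence interval for the mean.
#' @slot iterations per-iteration data.frame (iteration, threshold, n_voxels,
#'   train_d, test_d, n_test_patients, ok).
#' @slot nFailures iterations where no ROI could be formed.
#' @slot consensus the effect-size-weighted \linkS4class{ConsensusMap}.
#' @export
setClass("CVResult",
    representation(meanTestD = "numeric", ci95 = "numeric",
                   iterations = "data.frame", nFailures = "integer",
                   consensus = "ConsensusMap"))

setMethod("show", "CVResult", function(object) {
    k <- sum(object@iterations$ok)
    cat(sprintf(
        "CVResult: mean test d = %.3f (95%% CI [%.3f, %.3f]) over %d iterations (%d failed)\n",
        object@meanTestD, object@ci95[1], object@ci95[2], k,
        object@nFailures))
})

#' Planted atrophy focus
#'
#' One spherical region of accelerated volume loss planted in patient maps.
#'
#' @slot center world-mm coordinates of the nominal focus centre.
#' @slot radiusMm focus radius in mm (> 0).
#' @slot meanRate mean annual rate of change inside the focus (1/year,
#'   negative = contraction).
#' @slot betweenSubjectSd between-subject SD of the per-subject focus rate.
#' @slot profile "uniform-sphere" or "gaussian-falloff".
#' @export
setClass("AtrophyFocus",
    representation(center = "numeric", radiusMm = "numeric",
                   meanRate = "numeric", betweenSubjectSd = "numeric",
                   profile = "character"))

setValidity("AtrophyFocus", function(object) {
    msg <- character()
    if (length(object@center) != 3L) msg <- c(msg, "center must be length 3")
    if (object@radiusMm <= 0) msg <- c(msg, "radiusMm must be > 0")
    if (object@betweenSubjectSd < 0) msg <- c(msg, "betweenSubjectSd must be >= 0")
    if (!object@profile %in% c("uniform-sphere", "gaussian-falloff"))
        msg <- c(msg, "unknown profile")
    if (length(msg)) msg else TRUE
})

#' @rdname AtrophyFocus-class
#' @param center,radiusMm,meanRate,betweenSubjectSd,profile see slots.
#' @export
AtrophyFocus <- function(center, radiusMm, meanRate,
                         betweenSubjectSd = 0,
                         profile = c("uniform-sphere", "gaussian-falloff")) {
    new("AtrophyFocus", center = as.numeric(center),
        radiusMm = as.numeric(radiusMm), meanRate = as.numeric(meanRate),
        betweenSubjectSd = as.numeric(betweenSubjectSd),
        profile = match.arg(profile))
}

#' Synthetic cohort specification
#'
#' Defines the generative model for a synthetic change-map cohort: control
#' maps are i.i.d. voxel noise around \code{controlDriftMean}; patient maps
#' additionally receive, inside each focus (rigidly translated per subject by
#' a 3-D Gaussian jitter), a per-subject draw of the focus rate.
#' \code{jitterSdMm} is the between-subject spatial-heterogeneity knob.
#'
#' @slot grid target \linkS4class{VoxelGrid}.
#' @slot nControls,nPatients group sizes (each >= 2).
#' @slot foci list of \linkS4class{AtrophyFocus}.
#' @slot jitterSdMm per-axis SD (mm) of the per-subject rigid translation of
#'   all foci.
#' @slot voxelNoiseSd i.i.d. Gaussian voxel noise SD (1/year).
#' @slot controlDriftMean global mean annual change in controls (1/year).
#' @slot subjectDriftSd SD (1/year) of a per-subject whole-map rate offset
#'   applied to every subject (both groups): global between-subject
#'   variability independent of the focal signal.
#' @slot heterogeneityFwhmMm FWHM (mm) of the smooth per-subject random field
#'   that modulates each focus by its between-subject SD -- the spatial scale
#'   of within-region atrophy heterogeneity.
#' @slot smoothFwhmMm optional Gaussian FWHM (mm) applied to the noise field;
#'   0 disables (the default; the analysis itself never smooths).
#' @slot patientGroup group label given to patients (e.g. "svPPA").
#' @slot seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @export
setClass("SyntheticSpec",
    representation(grid = "VoxelGrid", nControls = "integer",
        nPatients = "integer", foci = "list", jitterSdMm = "numeric",
        voxelNoiseSd = "numeric", controlDriftMean = "numeric",
        subjectDriftSd = "numeric", heterogeneityFwhmMm = "numeric",
        smoothFwhmMm = "numeric", patientGroup = "character",
        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nControls < 2L || object@nPatients < 2L)
        msg <- c(msg, "need at least 2 subjects per group")
    if (object@voxelNoiseSd < 0) msg <- c(msg, "voxelNoiseSd must be >= 0")
    if (object@jitterSdMm < 0) msg <- c(msg, "jitterSdMm must be >= 0")
    if (object@subjectDriftSd < 0) msg <- c(msg, "subjectDriftSd must be >= 0")
    if (object@heterogeneityFwhmMm <= 0)
        msg <- c(msg, "heterogeneityFwhmMm must be > 0")
    if (!all(vapply(object@foci, is, TRUE, "AtrophyFocus")))
        msg <- c(msg, "foci must be AtrophyFocus objects")
    if (length(msg)) msg else TRUE
})

#' @rdname SyntheticSpec-class
#' @param grid,nControls,nPatients,foci,jitterSdMm,voxelNoiseSd see slots.
#' @param controlDriftMean,subjectDriftSd,heterogeneityFwhmMm see slots.
#' @param smoothFwhmMm,patientGroup,seed see slots.
#' @export
SyntheticSpec <- function(grid = VoxelGrid(c(32L, 32L, 32L), 1.5),
                          nControls = 30L, nPatients = 30L, foci = list(),
                          jitterSdMm = 0, voxelNoiseSd = 0.01,
                          controlDriftMean = 0, subjectDriftSd = 0.01,
                          heterogeneityFwhmMm = 6, smoothFwhmMm = 0,
                          patientGroup = "custom", seed = 1L) {
    new("SyntheticSpec", grid = grid, nControls = as.integer(nControls),
        nPatients = as.integer(nPatients), foci = foci,
        jitterSdMm = as.numeric(jitterSdMm),
        voxelNoiseSd = as.numeric(voxelNoiseSd),
        controlDriftMean = as.numeric(controlDriftMean),
        subjectDriftSd = as.numeric(subjectDriftSd),
        heterogeneityFwhmMm = as.numeric(heterogeneityFwhmMm),
        smoothFwhmMm = as.numeric(smoothFwhmMm),
        patientGroup = patientGroup, seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d HC + %d %s, %d foci, jitter %.1f mm, noise sd %.3g/yr, seed %d\n",
        object@nControls, object@nPatients, object@patientGroup,
        length(object@foci), object@jitterSdMm, object@voxelNoiseSd,
        object@seed))
})

#' Labelled atlas volume for a priori ROIs
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot labels integer 3-D array of region labels (0 = background).
#' @slot labelTable data.frame with columns label, name.
#' @export
setClass("AtlasVolume",
    representation(grid = "VoxelGrid", labels = "array",
                   labelTable = "data.frame"))

setValidity("AtlasVolume", function(object) {
    if (!identical(dim(object@labels), as.integer(object@grid@shape)))
        return("labels shape must equal grid shape")
    if (min(object@labels) < 0) return("labels must be >= 0")
    if (anyDuplicated(object@labelTable$name)) return("names must be unique")
    TRUE
})

#' @rdname AtlasVolume-class
#' @param grid,labels,labelTable see slots.
#' @export
AtlasVolume <- function(grid, labels, labelTable) {
    new("AtlasVolume", grid = grid,
        labels = array(as.integer(labels), dim = grid@shape),
        labelTable = labelTable)
}

#' Two-arm trial design
#'
#' @slot alpha two-sided type-I error rate.
#' @slot power target power.
#' @slot reduction treatment effect as a fraction of the annual rate of
#'   change (a 20 or 40 percent slowing is 0.2 or 0.4).
#' @export
setClass("TrialDesign",
    representation(alpha = "numeric", power = "numeric",
                   reduction = "numeric"))

setValidity("TrialDesign", function(object) {
    ok <- function(x) length(x) == 1 && x > 0 && x < 1
    if (!ok(object@alpha)) return("alpha must be in (0, 1)")
    if (!ok(object@power)) return("power must be in (0, 1)")
    if (!ok(object@reduction)) return("reduction must be in (0, 1)")
    TRUE
})

#' @rdname TrialDesign-class
#' @param reduction,alpha,power see slots; 1:1 allocation is assumed.
#' @export
TrialDesign <- function(reduction, alpha = 0.05, power = 0.8) {
    new("TrialDesign", alpha = alpha, power = power, reduction = reduction)
}

#' Per-arm sample-size result
#'
#' @slot nPerArm smallest per-arm n with power at or above the design power.
#' @slot method "noncentral-t" or "normal-approx".
#' @slot achievedPower power of the test at nPerArm.
#' @slot capped TRUE when the search hit the configured cap.
#' @export
setClass("SampleSizeResult",
    representation(nPerArm = "integer", method = "character",
                   achievedPower = "numeric", capped = "logical"))

setMethod("show", "SampleSizeResult", function(object) {
    cat(sprintf("SampleSizeResult: n = %d per arm (%s, achieved power %.3f%s)\n",
        object@nPerArm, object@method, object@achievedPower,
        if (object@capped) ", CAPPED" else ""))
})
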