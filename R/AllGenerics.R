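#' @rdname RateMapCohort
#' @param x a \linkS4class{RateMapCohort} (or object carrying a grid).
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname RateMapCohort
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' @rdname RateMapCohort
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname RateMapCohort
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname RateMapCohort
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname RateMapCohort
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))

#' @rdname RateMapCohort
#' @param value replacement value.
#' @export
setGeneric("analysisMask<-", function(x, value) standardGeneric("analysisMask<-"))

#' Annualize a change field
#'
#' Divides relative volume-change values by the interscan interval in years,
#' turning a between-scan change map into an annual rate-of-change map.
#'
#' @param x a numeric array/vector of relative change values, or a
#'   \linkS4class{RateMapCohort} (each subject divided by its own interval).
#' @param intervalYears positive interscan interval in years (ignored for
#'   cohorts, which carry their own).
#' @return The annualized object, same shape as the input.
#' @examples
#' annualize(c(-0.05, -0.02), intervalYears = 0.5)  # -0.10, -0.04 per year
#' @export
setGeneric("annualize", function(x, intervalYears) standardGeneric("annualize"))

#' Apply a gray-matter probability mask
#'
#' Multiplies change values voxel-by-voxel by the gray-matter probability and
#' defines the binary analysis mask as the voxels whose probability reaches
#' \code{inclusionThreshold}. Voxels outside the analysis mask are excluded
#' from all downstream statistics.
#'
#' @param x a \linkS4class{RateMapCohort} or a 3-D numeric array.
#' @param gm a \linkS4class{GrayMatterMap} on the same grid.
#' @param inclusionThreshold probability cutoff in [0, 1] for the analysis
#'   mask (default 0.1).
#' @return For a cohort: the masked cohort with \code{analysisMask()} set.
#'   For an array: list(values, mask).
#' @export
setGeneric("applyGMMask",
    function(x, gm, inclusionThreshold = 0.1) standardGeneric("applyGMMask"))

setMethod("voxelGrid", "RateMapCohort",
    function(x) S4Vectors::metadata(x)$grid)

setMethod("rateMatrix", "RateMapCohort",
    function(x) SummarizedExperiment::assay(x, "rate"))

setMethod("subjectIds", "RateMapCohort",
    function(x) SummarizedExperiment::colData(x)$subject_id)

setMethod("groups", "RateMapCohort",
    function(x) SummarizedExperiment::colData(x)$group)

setMethod("intervals", "RateMapCohort",
    function(x) SummarizedExperiment::colData(x)$interval_years)

setMethod("analysisMask", "RateMapCohort",
    function(x) S4Vectors::metadata(x)$analysisMask)

setMethod("analysisMask<-", "RateMapCohort", function(x, value) {
    S4Vectors::metadata(x)$analysisMask <- .flattenMask(value, voxelGrid(x))
    x
})

#' Extract one subject's map as a 3-D array
#'
#' @param x a \linkS4class{RateMapCohort}.
#' @param subject subject id or column index.
#' @return 3-D numeric array on the cohort grid.
#' @export
subjectVolume <- function(x, subject) {
    array(rateMatrix(x)[, subject], dim = voxelGrid(x)@shape)
}
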