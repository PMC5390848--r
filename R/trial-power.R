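## Per-arm sample sizes for a 1:1 placebo-controlled trial whose endpoint is
## the annual rate of ROI volume change, plus the comparison machinery
## against a priori anatomical ROIs.

## Exact power of the two-sided two-sample t test at per-arm n, standardized
## difference delta, via the noncentral t distribution.
.tTestPower <- function(n, delta, alpha = 0.05) {
    df <- 2 * n - 2
    ncp <- delta * sqrt(n / 2)
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

#' Per-arm sample size from an effect size
#'
#' For a hypothetical 1:1 placebo-controlled trial whose treatment slows the
#' annual rate of change by the fraction \code{reduction}, the standardized
#' treated-vs-placebo difference is delta = reduction x |d| (the SD is
#' anchored on the patient group through d itself). Returns the smallest
#' per-arm n at which the two-sided two-sample t test reaches the design
#' power, computed exactly with the noncentral t distribution, or with the
#' classic normal approximation 2 (z_{1-alpha/2} + z_{power})^2 / delta^2.
#'
#' @param d effect size (sign is ignored; must be nonzero).
#' @param design a \linkS4class{TrialDesign}.
#' @param method "noncentral-t" (exact, the default) or "normal-approx".
#' @param cap largest n searched (default 1e6); results at the cap are
#'   flagged.
#' @return A \linkS4class{SampleSizeResult}.
#' @examples
#' nPerArm(-0.98, TrialDesign(reduction = 0.4))
#' @export
nPerArm <- function(d, design, method = c("noncentral-t", "normal-approx"),
                    cap = 1e6) {
    method <- match.arg(method)
    if (d == 0) stop("effect size must be nonzero")
    delta <- design@reduction * abs(d)
    if (method == "normal-approx") {
        z <- qnorm(1 - design@alpha / 2) + qnorm(design@power)
        n <- ceiling(2 * (z / delta)^2)
        capped <- n > cap
        n <- min(n, cap)
        achieved <- pnorm(delta * sqrt(n / 2) - qnorm(1 - design@alpha / 2))
        return(new("SampleSizeResult", nPerArm = as.integer(n),
                   method = method, achievedPower = achieved,
                   capped = capped))
    }
    # bracket by doubling, then bisect for the smallest n with power >= target
    lo <- 2L; hi <- 2L
    while (.tTestPower(hi, delta, design@alpha) < design@power && hi < cap)
        hi <- min(as.integer(cap), hi * 2L)
    if (.tTestPower(hi, delta, design@alpha) < design@power) {
        return(new("SampleSizeResult", nPerArm = as.integer(cap),
                   method = method,
                   achievedPower = .tTestPower(cap, delta, design@alpha),
                   capped = TRUE))
    }
    while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (.tTestPower(mid, delta, design@alpha) >= design@power)
            hi <- mid
        else
            lo <- mid + 1L
    }
    new("SampleSizeResult", nPerArm = as.integer(lo), method = method,
        achievedPower = .tTestPower(lo, delta, design@alpha),
        capped = FALSE)
}

#' Cohen's d of an a priori (atlas-defined) ROI
#'
#' Pools the atlas voxels carrying the selected labels (intersected with the
#' cohort's analysis mask when one is set) and computes the same
#' pooled-SD Cohen's d of ROI-mean annual change as the data-driven pipeline,
#' so a priori and data-driven ROIs are directly comparable.
#'
#' @param atlas an \linkS4class{AtlasVolume} on the cohort grid.
#' @param labels integer labels or region names to include.
#' @param cohort a \linkS4class{RateMapCohort}.
#' @param patients,controls group labels.
#' @return signed Cohen's d.
#' @export
aprioriROID <- function(atlas, labels, cohort, patients, controls = "HC") {
    if (is.character(labels))
        labels <- atlas@labelTable$label[match(labels, atlas@labelTable$name)]
    if (any(is.na(labels)) || length(labels) == 0L)
        stop("unknown or empty label selection")
    roi <- as.vector(atlas@labels) %in% labels
    am <- analysisMask(cohort)
    if (!is.null(am)) roi <- roi & am
    if (!any(roi)) stop("selected labels contain no analysis-mask voxels")
    cohensD(roi, cohort, patients, controls)
}

#' Relative sample-size reduction
#'
#' @param nCandidate,nReference per-arm sample sizes (both >= 1).
#' @return list(percent = 100 * (1 - nCandidate / nReference),
#'   percentRounded = nearest integer for reporting).
#' @examples
#' relativeReduction(118, 170)  # 31 percent
#' @export
relativeReduction <- function(nCandidate, nReference) {
    stopifnot(nCandidate >= 1, nReference >= 1)
    p <- 100 * (1 - nCandidate / nReference)
    list(percent = p, percentRounded = as.integer(round(p)))
}

#' Sample-size comparison table
#'
#' Applies \code{\link{nPerArm}} to every (measure, design) pair and flags
#' the smallest per-arm n within each design column. Rows are ordered by
#' measure name so the table does not depend on input order.
#'
#' @param effectSizes named numeric vector of effect sizes (one per ROI or
#'   measure).
#' @param designs list of \linkS4class{TrialDesign} objects.
#' @param ... passed to \code{\link{nPerArm}}.
#' @return data.frame with columns measure, reduction, alpha, power,
#'   n_per_arm, is_min.
#' @export
sampleSizeTable <- function(effectSizes, designs, ...) {
    stopifnot(!is.null(names(effectSizes)))
    rows <- list()
    for (dg in designs) {
        n <- vapply(effectSizes, function(d)
            nPerArm(d, dg, ...)@nPerArm, integer(1))
        rows[[length(rows) + 1L]] <- data.frame(
            measure = names(effectSizes), reduction = dg@reduction,
            alpha = dg@alpha, power = dg@power, n_per_arm = n,
            is_min = n == min(n))
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$reduction, out$measure), ]
    rownames(out) <- NULL
    out
}
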