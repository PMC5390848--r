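#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical arrays/vectors of equal length.
#' @return 2|a & b| / (|a| + |b|); NaN when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
    a <- as.logical(a); b <- as.logical(b)
    stopifnot(length(a) == length(b))
    2 * sum(a & b) / (sum(a) + sum(b))
}

#' Threshold a consensus map into a binary ROI
#'
#' @param consensus a \linkS4class{ConsensusMap}.
#' @param cut weight cutoff in [0, 1].
#' @return logical 3-D array of voxels with weight >= cut.
#' @export
consensusMask <- function(consensus, cut = 0.5) {
    consensus@weights >= cut
}
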