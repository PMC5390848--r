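#' Write a 3-D volume to NIfTI-1
#'
#' @param values 3-D numeric array.
#' @param grid the \linkS4class{VoxelGrid} supplying affine and voxel size.
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type: "double" (exact round-trip, the
#'   default for rate maps), "float" (consensus maps) or "uint8" (masks).
#' @return the path, invisibly.
#' @export
writeVolume <- function(values, grid, path,
                        datatype = c("double", "float", "uint8")) {
    datatype <- match.arg(datatype)
    arr <- array(if (datatype == "uint8") as.integer(values)
                 else as.numeric(values), dim = grid@shape)
    attr(arr, "pixdim") <- grid@voxelSize
    img <- RNifti::asNifti(arr, datatype = datatype)
    img <- RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
    img <- RNifti::`qform<-`(img, structure(grid@affine, code = 2L))
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a 3-D volume from NIfTI-1
#'
#' @param path a .nii/.nii.gz file.
#' @return list(values = 3-D array, grid = \linkS4class{VoxelGrid}).
#' @export
readVolume <- function(path) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (is.null(d)) d <- length(img)
    if (length(d) > 3L)
        stop("expected a 3-D volume, got ", length(d), "-D: ", path)
    d <- c(d, rep(1L, 3L - length(d)))  # NIfTI drops trailing unit dims
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = c(4L, 4L))
    vs <- rep_len(as.numeric(RNifti::pixdim(img)), 3L)
    vs[vs <= 0] <- 1
    grid <- new("VoxelGrid", shape = as.integer(d),
                voxelSize = vs, affine = aff)
    list(values = array(as.numeric(img), dim = d), grid = grid)
}

.sameGrid <- function(a, b, tol = 1e-4) {
    identical(a@shape, b@shape) &&
        max(abs(a@affine - b@affine)) < tol
}

#' Read a change-map cohort from a manifest
#'
#' The manifest is a CSV with columns \code{subject_id}, \code{group},
#' \code{interval_years} and \code{path} (NIfTI volume, absolute or relative
#' to the manifest). All volumes must share one grid; subject ids must be
#' unique and intervals positive.
#'
#' @param manifestPath CSV manifest path.
#' @param annualizeMaps divide each map by its interscan interval on load
#'   (default TRUE; set FALSE when the volumes are already rates).
#' @return A \linkS4class{RateMapCohort}.
#' @export
readCohort <- function(manifestPath, annualizeMaps = TRUE) {
    if (!file.exists(manifestPath))
        stop("manifest not found: ", manifestPath)
    man <- read.csv(manifestPath, stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "interval_years", "path")
    if (!all(need %in% names(man)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(man$subject_id))
        stop("duplicate subject_id in manifest: ",
             paste(unique(man$subject_id[duplicated(man$subject_id)]),
                   collapse = ", "))
    if (any(man$interval_years <= 0))
        stop("interscan intervals must be positive")
    paths <- ifelse(file.exists(man$path), man$path,
                    file.path(dirname(manifestPath), man$path))
    missing <- !file.exists(paths)
    if (any(missing))
        stop("missing volumes: ", paste(paths[missing], collapse = ", "))
    first <- readVolume(paths[1])
    grid <- first$grid
    rates <- matrix(NA_real_, prod(grid@shape), nrow(man))
    rates[, 1] <- as.vector(first$values)
    for (i in seq_len(nrow(man))[-1]) {
        v <- readVolume(paths[i])
        if (!.sameGrid(v$grid, grid))
            stop("grid mismatch for ", man$subject_id[i])
        rates[, i] <- as.vector(v$values)
    }
    if (annualizeMaps)
        rates <- sweep(rates, 2L, man$interval_years, "/")
    RateMapCohort(rates, grid, man$subject_id, man$group,
                  intervalYears = man$interval_years)
}

#' Write a cohort to NIfTI volumes plus a CSV manifest
#'
#' @param cohort a \linkS4class{RateMapCohort} (assumed annualized; intervals
#'   are recorded in the manifest but maps are written as-is, so the manifest
#'   should be re-read with \code{annualizeMaps = FALSE}).
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    grid <- voxelGrid(cohort)
    ids <- subjectIds(cohort)
    files <- file.path(dir, paste0(ids, "_rate.nii.gz"))
    for (i in seq_along(ids))
        writeVolume(rateMatrix(cohort)[, i], grid, files[i], "double")
    man <- data.frame(subject_id = ids, group = groups(cohort),
                      interval_years = intervals(cohort),
                      path = basename(files))
    manPath <- file.path(dir, "manifest.csv")
    write.csv(man, manPath, row.names = FALSE)
    invisible(manPath)
}

#' @rdname annualize
setMethod("annualize", signature(x = "numeric", intervalYears = "numeric"),
    function(x, intervalYears) {
        if (intervalYears <= 0) stop("intervalYears must be > 0")
        x / intervalYears
    })

#' @rdname annualize
setMethod("annualize", signature(x = "array", intervalYears = "numeric"),
    function(x, intervalYears) {
        if (intervalYears <= 0) stop("intervalYears must be > 0")
        x / intervalYears
    })

#' @rdname annualize
setMethod("annualize", signature(x = "RateMapCohort", intervalYears = "ANY"),
    function(x, intervalYears) {
        iv <- intervals(x)
        if (any(iv <= 0)) stop("intervals must be > 0")
        SummarizedExperiment::assay(x, "rate") <-
            sweep(rateMatrix(x), 2L, iv, "/")
        x
    })

#' @rdname applyGMMask
setMethod("applyGMMask", signature(x = "RateMapCohort", gm = "GrayMatterMap"),
    function(x, gm, inclusionThreshold = 0.1) {
        if (!.sameGrid(voxelGrid(x), gm@grid))
            stop("gray-matter map grid does not match cohort grid")
        p <- as.vector(gm@probabilities)
        SummarizedExperiment::assay(x, "rate") <- rateMatrix(x) * p
        analysisMask(x) <- p >= inclusionThreshold
        x
    })

#' @rdname applyGMMask
setMethod("applyGMMask", signature(x = "array", gm = "GrayMatterMap"),
    function(x, gm, inclusionThreshold = 0.1) {
        if (!identical(dim(x), as.integer(gm@grid@shape)))
            stop("array shape does not match gray-matter map grid")
        list(values = x * gm@probabilities,
             mask = gm@probabilities >= inclusionThreshold)
    })
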