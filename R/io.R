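# Project container: a single serialized file holding the cine k-space and
# any derived groups (mask, truth, recon, reports), with explicit convention
# attributes (axis order, DC position, channel packing) so consumers never
# have to guess. Complex arrays round-trip bit-exactly.

containerConventions <- function() {
    list(format = "cineRAKI-container", version = "1",
         axisOrder = "slice,phase,coil,ky,kx",
         dcPosition = "floor(n/2) (0-based)",
         channelOrder = "Re(c1..cN), Im(c1..cN)")
}

#' Write a cine container
#'
#' Stores the k-space stack plus optional groups (\code{mask}, \code{truth},
#' \code{recon}, \code{report}, \code{weights}) with convention attributes.
#'
#' @param path output file path.
#' @param kspace a \linkS4class{CineKSpace} or \linkS4class{CineTruth} (the
#'   latter stores its ground truth too).
#' @param mask optional \linkS4class{SamplingMask}.
#' @param recon optional \linkS4class{ReconResult}.
#' @param report optional \code{MetricsReport}.
#' @param extra optional named list of additional groups.
#' @return \code{path}, invisibly.
#' @export
writeCineContainer <- function(path, kspace, mask = NULL, recon = NULL,
                               report = NULL, extra = list()) {
    obj <- list(conventions = containerConventions())
    if (is(kspace, "CineTruth")) {
        obj$kspace <- kspace@kspace@kdata
        obj$truth <- list(sosImages = kspace@sosImages, heartROI = kspace@heartROI,
                          config = kspace@config)
    } else if (is(kspace, "CineKSpace")) {
        obj$kspace <- kspace@kdata
    } else stop("kspace must be a CineKSpace or CineTruth", call. = FALSE)
    if (!is.null(mask)) obj$mask <- mask
    if (!is.null(recon)) obj$recon <- list(images = recon@images,
                                           timing = recon@timing,
                                           method = recon@method)
    if (!is.null(report)) obj$report <- report
    for (nm in names(extra)) obj[[nm]] <- extra[[nm]]
    saveRDS(obj, path)
    invisible(path)
}

#' Read a cine container
#'
#' @param path container file.
#' @return list with \code{kspace} (\linkS4class{CineKSpace}) and any stored
#'   groups (\code{mask}, \code{truth}, \code{recon}, \code{report}, ...).
#' @export
readCineContainer <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    obj <- tryCatch(readRDS(path), error = function(e)
        stop("cannot parse container '", path, "': ", conditionMessage(e),
             call. = FALSE))
    if (!identical(obj$conventions$format, "cineRAKI-container"))
        stop("not a cineRAKI container: ", path, call. = FALSE)
    obj$kspace <- new("CineKSpace", kdata = obj$kspace)
    obj
}

#' Read multi-slice cine k-space data
#'
#' The \code{"container"} dialect reads the package's own container format.
#' An ISMRMRD/HDF5 reading path is not built into this package; requesting
#' \code{dialect = "ismrmrd"} fails with a clear diagnostic so pipelines can
#' degrade gracefully.
#'
#' @param path input file.
#' @param dialect \code{"container"} or \code{"ismrmrd"}.
#' @return for \code{"container"}: a list as from [readCineContainer()].
#' @export
readCine <- function(path, dialect = c("container", "ismrmrd")) {
    dialect <- match.arg(dialect)
    if (dialect == "ismrmrd")
        stop("ISMRMRD/HDF5 input is not supported by this installation; ",
             "convert the acquisition to the container format first",
             call. = FALSE)
    readCineContainer(path)
}
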