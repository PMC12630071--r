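#' @import methods
NULL

#' CineKSpace: multi-slice multi-phase multi-coil complex k-space
#'
#' The central container of the package: a complex 5-D array indexed
#' \code{[slice, phase, coil, ky, kx]}, with the DC sample at row
#' \code{floor(ny/2)} (0-based) of the phase-encode (\code{ky}) axis and at
#' column \code{floor(nx/2)} of the readout (\code{kx}) axis.
#'
#' @slot kdata complex 5-D array \code{[slice, phase, coil, ky, kx]}.
#' @export
setClass("CineKSpace", representation(kdata = "array"), validity = function(object) {
    d <- dim(object@kdata)
    if (length(d) != 5L)
        return("kdata must be a 5-D array [slice, phase, coil, ky, kx]")
    if (!is.complex(object@kdata))
        return("kdata must be complex")
    if (any(!is.finite(Re(object@kdata))) || any(!is.finite(Im(object@kdata))))
        return("kdata must be finite")
    TRUE
})

#' SamplingMask: uniform undersampling pattern with centered ACS block
#'
#' Phase-encode sampling pattern for retrospective uniform undersampling:
#' every row \code{r} (0-based) with \code{(r - latticeOffset) %% R == 0} is
#' acquired, unioned with a contiguous fully sampled centered ACS interval.
#'
#' @slot acquired logical vector of length \code{ny}; element \code{r + 1}
#'   says whether 0-based row \code{r} is acquired.
#' @slot R integer acceleration rate.
#' @slot nACS integer number of ACS lines.
#' @slot acsStart,acsEnd 0-based half-open ACS row interval \code{[acsStart, acsEnd)}.
#' @slot latticeOffset integer lattice alignment (0: row 0 acquired).
#' @export
setClass("SamplingMask", representation(
    acquired = "logical", R = "integer", nACS = "integer",
    acsStart = "integer", acsEnd = "integer", latticeOffset = "integer"
), validity = function(object) {
    ny <- length(object@acquired)
    if (ny < 1L) return("empty mask")
    if (object@R < 1L) return("R must be >= 1")
    if (object@acsStart < 0L || object@acsEnd > ny || object@acsEnd < object@acsStart)
        return("ACS interval out of bounds")
    acs <- seq.int(object@acsStart + 1L, length.out = object@acsEnd - object@acsStart)
    if (length(acs) && !all(object@acquired[acs]))
        return("ACS rows must all be acquired")
    lat <- which(((seq_len(ny) - 1L) - object@latticeOffset) %% object@R == 0L)
    if (!all(object@acquired[lat]))
        return("all lattice rows must be acquired")
    TRUE
})

#' PhantomConfig: parameters of the synthetic cine phantom
#'
#' @slot ny,nx image/k-space matrix size (phase-encode, readout).
#' @slot nSlices,nPhases,nCoils stack geometry.
#' @slot heartCenter numeric length-2, (row, col) 0-based pixel coordinates of
#'   the beating-heart disc.
#' @slot heartRadiusRange numeric length-2, (min, max) disc radius in pixels
#'   over the cardiac cycle.
#' @slot sliceDrift nonnegative per-slice sensitivity/anatomy drift rate
#'   (radians of coil-ring rotation per slice).
#' @slot noiseStd complex-Gaussian noise std per k-space sample, relative to
#'   the peak (DC-region) k-space magnitude of each frame.
#' @slot coilBandlimit,objectBandlimit optional odd integers (NA to disable):
#'   confine the coil-sensitivity / coil-image k-space support to a centered
#'   square block of this side length (used by exact-recovery analyses).
#' @slot profileType coil profile family: \code{"gaussian"} (smooth
#'   ring-coil falloff, the realistic default), \code{"uniform"} (all-ones),
#'   or \code{"harmonic"} (single low-order k-space harmonic per coil with
#'   constant sum-of-squares; the family for which a linear interpolation
#'   kernel is exactly realizable).
#' @slot seed integer master seed for all phantom randomness.
#' @export
setClass("PhantomConfig", representation(
    ny = "integer", nx = "integer", nSlices = "integer", nPhases = "integer",
    nCoils = "integer", heartCenter = "numeric", heartRadiusRange = "numeric",
    sliceDrift = "numeric", noiseStd = "numeric",
    coilBandlimit = "integer", objectBandlimit = "integer",
    profileType = "character", seed = "integer"
), validity = function(object) {
    if (!object@profileType %in% c("gaussian", "uniform", "harmonic"))
        return("unknown profileType")
    if (object@ny < 32L || object@nx < 32L) return("ny and nx must be >= 32")
    if (object@nCoils < 1L) return("nCoils must be >= 1")
    if (object@nSlices < 1L || object@nPhases < 1L) return("nSlices and nPhases must be >= 1")
    if (length(object@heartCenter) != 2L) return("heartCenter must have length 2")
    if (any(object@heartCenter < 0) || object@heartCenter[1] >= object@ny ||
        object@heartCenter[2] >= object@nx)
        return("heartCenter outside the image")
    if (length(object@heartRadiusRange) != 2L || any(object@heartRadiusRange <= 0) ||
        diff(object@heartRadiusRange) < 0)
        return("heartRadiusRange must be positive and nondecreasing")
    if (object@sliceDrift < 0) return("sliceDrift must be >= 0")
    if (object@noiseStd < 0) return("noiseStd must be >= 0")
    TRUE
})

#' CineTruth: fully sampled synthetic cine stack with ground truth
#'
#' @slot kspace \linkS4class{CineKSpace}, fully sampled (noisy if requested).
#' @slot coilImages complex array \code{[slice, phase, coil, ny, nx]} of
#'   noise-free coil images.
#' @slot sosImages real array \code{[slice, phase, ny, nx]} of root-sum-of-squares
#'   reference images.
#' @slot heartROI ROI record (list with 0-based half-open row/col intervals).
#' @slot config the generating \linkS4class{PhantomConfig}.
#' @export
setClass("CineTruth", representation(
    kspace = "CineKSpace", coilImages = "array", sosImages = "array",
    heartROI = "list", config = "PhantomConfig"
))

#' NetworkSpec: layer geometry of a scan-specific k-space network
#'
#' @slot method one of \code{"SRAKI"}, \code{"RAKI"}, \code{"RRAKI"}.
#' @slot layers ordered list of layer specs (each a list with \code{inCh},
#'   \code{outCh}, \code{ky}, \code{kx}, \code{bias}, \code{activation}).
#' @slot linearPath for RRAKI, the parallel single linear layer spec (list), else empty.
#' @slot nCoils integer coil count; first input and last output have
#'   \code{2 * nCoils} channels.
#' @export
setClass("NetworkSpec", representation(
    method = "character", layers = "list", linearPath = "list", nCoils = "integer"
), validity = function(object) {
    if (!object@method %in% c("SRAKI", "RAKI", "RRAKI")) return("unknown method")
    if (!length(object@layers)) return("no layers")
    nc2 <- 2L * object@nCoils
    if (object@layers[[1]]$inCh != nc2) return("first layer must take 2*nCoils channels")
    if (object@layers[[length(object@layers)]]$outCh != nc2)
        return("last layer must emit 2*nCoils channels")
    for (l in object@layers) {
        if (l$ky %% 2L == 0L || l$kx %% 2L == 0L) return("kernel dims must be odd")
        if (l$inCh < 1L || l$outCh < 1L) return("channel counts must be >= 1")
    }
    TRUE
})

#' WeightSet: trained weights of a scan-specific network
#'
#' @slot method network method tag.
#' @slot spec the \linkS4class{NetworkSpec} the weights realize.
#' @slot params list of per-layer parameters (\code{W} matrix
#'   \code{[ky*kx*inCh, outCh]}, \code{b} vector); for RRAKI, element
#'   \code{linear} holds the parallel path parameters.
#' @slot normScale positive k-space normalization scale used at training.
#' @slot provenance list with \code{slice}, \code{phase} (may be vectors for
#'   jointly trained models) and the sampling scheme.
#' @slot lossTrace numeric per-epoch training loss.
#' @export
setClass("WeightSet", representation(
    method = "character", spec = "NetworkSpec", params = "list",
    normScale = "numeric", provenance = "list", lossTrace = "numeric"
), validity = function(object) {
    if (object@normScale <= 0) return("normScale must be positive")
    ok <- vapply(object@params, function(p)
        all(is.finite(p$W)) && all(is.finite(p$b)), logical(1))
    if (!all(ok)) return("non-finite parameters")
    TRUE
})

#' GrappaWeights: calibrated GRAPPA interpolation kernel
#'
#' @slot weights list of complex matrices, one per missing-line offset
#'   \code{d = 1..R-1}; each maps the flattened source taps
#'   \code{[ky-tap, kx-tap, coil]} to the \code{nCoils} target values.
#' @slot spec list with \code{nSourceLines}, \code{kxTaps}, \code{R}, \code{nCoils}.
#' @slot provenance list with \code{slice}, \code{phase} trained.
#' @export
setClass("GrappaWeights", representation(
    weights = "list", spec = "list", provenance = "list"
), validity = function(object) {
    if (length(object@weights) != object@spec$R - 1L)
        return("need one weight block per missing offset")
    TRUE
})

#' ReconResult: reconstructed cine stack with timing breakdown
#'
#' @slot images real array \code{[slice, phase, ny, nx]} of SoS magnitude
#'   reconstructions.
#' @slot timing data.frame with one row per frame: \code{slice}, \code{phase},
#'   \code{load_s}, \code{train_s}, \code{eval_s}, \code{recon_s} (training
#'   time is attributed to the trained frame of each plan entry).
#' @slot plan the training plan executed (list of entries).
#' @slot weights list of trained weight sets (one per plan entry).
#' @slot method reconstruction method tag.
#' @export
setClass("ReconResult", representation(
    images = "array", timing = "data.frame", plan = "list",
    weights = "list", method = "character"
), validity = function(object) {
    if (any(object@images < 0)) return("SoS images must be nonnegative")
    need <- c("slice", "phase", "load_s", "train_s", "eval_s", "recon_s")
    if (!all(need %in% names(object@timing))) return("incomplete timing table")
    if (any(unlist(object@timing[, c("load_s", "train_s", "eval_s", "recon_s")]) < 0))
        return("negative timing")
    TRUE
})

setMethod("show", "CineKSpace", function(object) {
    d <- dim(object@kdata)
    cat(sprintf("CineKSpace: %d slice(s) x %d phase(s) x %d coil(s), %d x %d k-space\n",
                d[1], d[2], d[3], d[4], d[5]))
})

setMethod("show", "SamplingMask", function(object) {
    cat(sprintf("SamplingMask: ny=%d, R=%d, ACS [%d,%d) (%d lines), %d/%d rows acquired\n",
                length(object@acquired), object@R, object@acsStart, object@acsEnd,
                object@nACS, sum(object@acquired), length(object@acquired)))
})

setMethod("show", "CineTruth", function(object) {
    cfg <- object@config
    cat(sprintf(
        "CineTruth: %d slice(s) x %d phase(s) x %d coil(s), %d x %d, noiseStd=%g, sliceDrift=%g\n",
        cfg@nSlices, cfg@nPhases, cfg@nCoils, cfg@ny, cfg@nx, cfg@noiseStd, cfg@sliceDrift))
})

setMethod("show", "NetworkSpec", function(object) {
    cat(sprintf("NetworkSpec: %s, %d coil(s), %d layer(s)%s, %d parameters\n",
                object@method, object@nCoils, length(object@layers),
                if (length(object@linearPath)) " + linear path" else "",
                countParameters(object)))
})

setMethod("show", "WeightSet", function(object) {
    pr <- object@provenance
    cat(sprintf("WeightSet: %s trained on slice %s, phase %s (final loss %.3g)\n",
                object@method,
                paste(pr$slice, collapse = ","), paste(pr$phase, collapse = ","),
                utils::tail(object@lossTrace, 1)))
})

setMethod("show", "ReconResult", function(object) {
    d <- dim(object@images)
    cat(sprintf("ReconResult (%s): %d slice(s) x %d phase(s), %d x %d; %d training(s), total train %.3gs\n",
                object@method, d[1], d[2], d[3], d[4], length(object@weights),
                sum(object@timing$train_s)))
})
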