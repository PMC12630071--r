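# Classic GRAPPA: least-squares calibration of a linear k-space interpolation
# kernel on the ACS, then completion of the missing phase-encode lines.
#
# Source geometry: nSourceLines acquired ky lines spaced R apart by kxTaps
# readout taps, across all coils; for each missing-line offset d in 1..R-1
# the target sits d rows below the ceiling(nSourceLines/2)-th source line.
# Column order of the flattened source vector is (ky tap, kx tap, coil) with
# the coil index fastest:  j = ((t_ky - 1) * kxTaps + t_kx - 1) * nCoils + c.

#' GRAPPA kernel geometry
#'
#' @param nSourceLines acquired ky source lines (spaced R apart); default 5.
#' @param kxTaps odd number of readout taps; default 5.
#' @param R acceleration rate the kernel is calibrated for.
#' @return list of class \code{"GrappaKernelSpec"}.
#' @export
grappaKernelSpec <- function(nSourceLines = 5L, kxTaps = 5L, R) {
    nSourceLines <- asInt(nSourceLines, "nSourceLines")
    kxTaps <- asInt(kxTaps, "kxTaps"); R <- asInt(R, "R")
    if (nSourceLines < 2L) stop("nSourceLines must be >= 2", call. = FALSE)
    if (kxTaps %% 2L == 0L) stop("kxTaps must be odd", call. = FALSE)
    if (R < 1L) stop("R must be >= 1", call. = FALSE)
    structure(list(nSourceLines = nSourceLines, kxTaps = kxTaps, R = R),
              class = "GrappaKernelSpec")
}

# 0-based row offsets of the source lines relative to the target row, for
# missing offset d: target = midSource + d, sources at j*R for j = 0..n-1.
grappaSourceOffsets <- function(spec, d) {
    midIdx <- as.integer(ceiling(spec$nSourceLines / 2)) - 1L   # 0-based
    (seq_len(spec$nSourceLines) - 1L) * spec$R - midIdx * spec$R - d
}

#' Calibrate GRAPPA weights on an ACS block
#'
#' For each missing-line offset, slides the source/target window across the
#' ACS, stacks the linear equations and solves the regularized least-squares
#' problem via the normal equations (Tikhonov ridge; the unregularized
#' solution is the Moore-Penrose least-squares fit).
#'
#' @param acs complex array \code{[nCoils, nACS, nx]}.
#' @param spec a \code{GrappaKernelSpec}.
#' @param ridge nonnegative ridge; \code{NULL} (default) uses
#'   \code{1e-6 * trace(A^H A) / nUnknowns}, \code{0} disables regularization.
#' @param provenance optional list tagging the trained (slice, phase).
#' @param acsStart optional 0-based global row index of the first ACS line.
#'   When given, only calibration windows whose source rows fall on the
#'   global acquired lattice are used (exactly the application geometry);
#'   by default all windows slide across the ACS, the standard choice, which
#'   assumes the interpolation relation is shift-invariant.
#' @return a \linkS4class{GrappaWeights}.
#' @export
grappaCalibrate <- function(acs, spec, ridge = NULL, provenance = list(),
                            acsStart = NULL) {
    d <- frameDims(acs)
    nC <- d[1]; nACS <- d[2]; nx <- d[3]
    if (all(abs(acs) == 0)) stop("singular system: all-zero ACS", call. = FALSE)
    R <- spec$R; nsl <- spec$nSourceLines; kxt <- spec$kxTaps
    half <- kxt %/% 2L
    span <- (nsl - 1L) * R
    if (nACS < span + 1L)
        stop(sprintf("calibration infeasible: need at least %d ACS lines, have %d",
                     span + 1L, nACS), call. = FALSE)
    if (nx < kxt) stop("calibration infeasible: readout narrower than kxTaps", call. = FALSE)
    nUnk <- nC * nsl * kxt
    weights <- vector("list", max(R - 1L, 0L))
    midIdx <- as.integer(ceiling(nsl / 2)) - 1L
    xs <- (half + 1L):(nx - half)             # kx centers with full support
    for (dd in seq_len(R - 1L)) {
        # window start rows r0 (0-based within ACS) with all sources + target inside
        tOff <- midIdx * R + dd
        r0max <- nACS - 1L - max(span, tOff)
        if (r0max < 0L)
            stop("calibration infeasible: ACS too small for this offset", call. = FALSE)
        r0s <- 0:r0max
        if (!is.null(acsStart)) {
            r0s <- r0s[((acsStart + r0s) %% R) == 0L]
            if (!length(r0s))
                stop("calibration infeasible: no lattice-aligned windows", call. = FALSE)
        }
        nEq <- length(r0s) * length(xs)
        A <- matrix(0i, nEq, nUnk)
        B <- matrix(0i, nEq, nC)
        row <- 0L
        for (r0 in r0s) {
            src <- r0 + (seq_len(nsl) - 1L) * R + 1L      # 1-based ACS rows
            tgt <- r0 + tOff + 1L
            idx <- row + seq_along(xs)
            col <- 0L
            for (ty in seq_len(nsl)) for (tx in seq_len(kxt)) {
                vals <- acs[, src[ty], xs + tx - half - 1L, drop = FALSE]
                A[idx, col + seq_len(nC)] <- t(array(vals, c(nC, length(xs))))
                col <- col + nC
            }
            B[idx, ] <- t(array(acs[, tgt, xs, drop = FALSE], c(nC, length(xs))))
            row <- row + length(xs)
        }
        AHA <- Conj(t(A)) %*% A
        AHB <- Conj(t(A)) %*% B
        lam <- if (is.null(ridge)) 1e-6 * Re(sum(diag(AHA))) / nUnk else ridge
        if (lam > 0) diag(AHA) <- diag(AHA) + lam
        W <- tryCatch(solve(AHA, AHB), error = function(e)
            stop("singular system in GRAPPA calibration (try ridge > 0): ",
                 conditionMessage(e), call. = FALSE))
        weights[[dd]] <- W
    }
    new("GrappaWeights", weights = weights,
        spec = list(nSourceLines = nsl, kxTaps = kxt, R = R, nCoils = nC),
        provenance = provenance)
}

#' Apply GRAPPA weights to fill missing k-space lines
#'
#' Each missing row is interpolated from acquired lattice rows only; sources
#' outside k-space are zero-padded; acquired rows are left untouched. The
#' inner product is accumulated tap by tap in a fixed order so results are
#' reproducible to the bit.
#'
#' @param weights a \linkS4class{GrappaWeights}.
#' @param zeroFilled complex array \code{[nCoils, ny, nx]} with missing rows zero.
#' @param mask the \linkS4class{SamplingMask} describing acquisition.
#' @return complex array with all rows filled.
#' @export
grappaApply <- function(weights, zeroFilled, mask) {
    d <- frameDims(zeroFilled)
    sp <- weights@spec
    if (sp$R != mask@R) stop("kernel R does not match mask R", call. = FALSE)
    if (sp$nCoils != d[1]) stop("coil count mismatch", call. = FALSE)
    if (length(mask@acquired) != d[2]) stop("mask ny mismatch", call. = FALSE)
    R <- sp$R
    if (R == 1L) return(zeroFilled)
    nC <- d[1]; ny <- d[2]; nx <- d[3]
    kxt <- sp$kxTaps; nsl <- sp$nSourceLines; half <- kxt %/% 2L
    out <- zeroFilled
    lattice <- ((seq_len(ny) - 1L) %% R) == 0L
    latticeData <- zeroFilled
    latticeData[, !lattice, ] <- 0i   # sources come from acquired lattice rows only
    for (m in which(!mask@acquired)) {
        m0 <- m - 1L
        dd <- m0 %% R
        if (dd == 0L) next
        offs <- grappaSourceOffsets(sp, dd)
        W <- weights@weights[[dd]]
        pred <- matrix(0i, nx, nC)
        col <- 0L
        for (ty in seq_len(nsl)) {
            srcRow <- m0 + offs[ty] + 1L
            rowVals <- if (srcRow >= 1L && srcRow <= ny)
                t(array(latticeData[, srcRow, ], c(nC, nx))) else matrix(0i, nx, nC)
            for (tx in seq_len(kxt)) {
                sh <- tx - half - 1L    # source column = x + sh, zero-padded
                if (sh == 0L) shifted <- rowVals
                else {
                    shifted <- matrix(0i, nx, nC)
                    if (sh > 0L) shifted[1:(nx - sh), ] <- rowVals[(1L + sh):nx, ]
                    else shifted[(1L - sh):nx, ] <- rowVals[1:(nx + sh), ]
                }
                for (cc in seq_len(nC)) {
                    j <- col + cc
                    pred <- pred + shifted[, cc] %o% W[j, ]
                }
                col <- col + nC
            }
        }
        out[, m, ] <- t(pred)
    }
    out
}

#' Full GRAPPA reconstruction of one frame
#'
#' Composition: extract ACS, calibrate, apply, enforce data consistency,
#' inverse Fourier transform, sum-of-squares combine.
#'
#' @param frame complex array \code{[nCoils, ny, nx]} (fully sampled or
#'   already undersampled; the mask is applied retrospectively).
#' @param mask a \linkS4class{SamplingMask}.
#' @param spec a \code{GrappaKernelSpec} (defaults to 5 x 5 at the mask's R).
#' @param ridge see [grappaCalibrate()].
#' @return list with \code{image} (real SoS matrix), \code{kspace}
#'   (completed complex frame) and \code{weights}.
#' @export
grappaReconstruct <- function(frame, mask, spec = grappaKernelSpec(R = mask@R),
                              ridge = NULL) {
    zf <- undersample(frame, mask)
    if (mask@R == 1L) {
        img <- sosCombine(ifft2c(zf))
        return(list(image = img, kspace = zf, weights = NULL))
    }
    acs <- extractACS(zf, mask)
    w <- grappaCalibrate(acs, spec, ridge)
    filled <- grappaApply(w, zf, mask)
    filled <- dataConsistency(filled, zf, mask)
    list(image = sosCombine(ifft2c(filled)), kspace = filled, weights = w)
}
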