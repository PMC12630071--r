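# Centered unitary Fourier transforms, coil combination, complex <-> channel
# packing, data consistency, and k-space normalization shared by all methods.
#
# Conventions (fixed package-wide):
#   * k-space frames are complex arrays [nCoils, ny, nx] with DC at 0-based
#     (floor(ny/2), floor(nx/2));
#   * FFTs are unitary (orthonormal scaling), so Parseval holds exactly and
#     PSNR is scale-stable between domains;
#   * channel stacks pack [Re(c1)..Re(cN), Im(c1)..Im(cN)].

frameDims <- function(k) {
    d <- dim(k)
    stopifnot2(length(d) == 3L, "expected a [nCoils, ny, nx] frame")
    d
}

applyFrame <- function(k, f) {
    d <- frameDims(k)
    out <- array(0i, d)
    for (cc in seq_len(d[1])) out[cc, , ] <- f(array(k[cc, , ], d[2:3]))
    out
}

#' Centered unitary 2-D FFT of a multi-coil frame
#'
#' Transforms coil images to k-space with orthonormal scaling and the DC
#' sample at 0-based \code{(floor(ny/2), floor(nx/2))}.
#'
#' @param img complex array \code{[nCoils, ny, nx]} of coil images.
#' @return complex array of the same shape (k-space).
#' @seealso [ifft2c()]
#' @export
fft2c <- function(img) {
    d <- frameDims(img)
    applyFrame(img, function(m) {
        y <- stats::fft(m[ifftshiftIdx(d[2]), ifftshiftIdx(d[3]), drop = FALSE])
        y[fftshiftIdx(d[2]), fftshiftIdx(d[3]), drop = FALSE] / sqrt(d[2] * d[3])
    })
}

#' Centered unitary inverse 2-D FFT of a multi-coil k-space frame
#'
#' @param k complex array \code{[nCoils, ny, nx]} of k-space data.
#' @return complex array of coil images, same shape.
#' @export
ifft2c <- function(k) {
    d <- frameDims(k)
    applyFrame(k, function(m) {
        y <- stats::fft(m[ifftshiftIdx(d[2]), ifftshiftIdx(d[3]), drop = FALSE],
                        inverse = TRUE)
        y[fftshiftIdx(d[2]), fftshiftIdx(d[3]), drop = FALSE] / sqrt(d[2] * d[3])
    })
}

#' Root-sum-of-squares coil combination
#'
#' @param coilImages complex (or real) array \code{[nCoils, ny, nx]}.
#' @return nonnegative real matrix \code{[ny, nx]}.
#' @export
sosCombine <- function(coilImages) {
    d <- frameDims(coilImages)
    m <- sqrt(apply(abs(coilImages)^2, c(2, 3), sum))
    dim(m) <- d[2:3]
    m
}

#' Split a complex frame into real/imaginary channels
#'
#' Packs \code{[nCoils, ny, nx]} complex data into a real channel stack
#' \code{[2*nCoils, ny, nx]} ordered \code{[Re(c1)..Re(cN), Im(c1)..Im(cN)]}.
#'
#' @param k complex array \code{[nCoils, ny, nx]}.
#' @return real array \code{[2*nCoils, ny, nx]}.
#' @seealso [mergeComplex()]
#' @export
splitComplex <- function(k) {
    d <- frameDims(k)
    out <- array(0, c(2L * d[1], d[2], d[3]))
    out[seq_len(d[1]), , ] <- Re(k)
    out[d[1] + seq_len(d[1]), , ] <- Im(k)
    out
}

#' Merge a real/imaginary channel stack back into a complex frame
#'
#' Exact inverse of [splitComplex()].
#'
#' @param ch real array \code{[2*nCoils, ny, nx]}.
#' @return complex array \code{[nCoils, ny, nx]}.
#' @export
mergeComplex <- function(ch) {
    d <- dim(ch)
    stopifnot2(length(d) == 3L, "expected a [2*nCoils, ny, nx] channel stack")
    if (d[1] %% 2L != 0L) stop("channel count must be even", call. = FALSE)
    n <- d[1] %/% 2L
    array(complex(real = ch[seq_len(n), , ], imaginary = ch[n + seq_len(n), , ]),
          c(n, d[2], d[3]))
}

#' Enforce consistency with the measured k-space rows
#'
#' Replaces predicted values on acquired phase-encode rows with the measured
#' values, leaving predictions on missing rows untouched.
#'
#' @param predicted,measured complex arrays \code{[nCoils, ny, nx]}.
#' @param mask a \linkS4class{SamplingMask} with \code{ny} matching.
#' @return complex array, same shape.
#' @export
dataConsistency <- function(predicted, measured, mask) {
    dp <- frameDims(predicted); dm <- frameDims(measured)
    if (!all(dp == dm)) stop("shape mismatch between predicted and measured", call. = FALSE)
    if (length(mask@acquired) != dp[2])
        stop("mask ny does not match k-space phase-encode size", call. = FALSE)
    out <- predicted
    out[, mask@acquired, ] <- measured[, mask@acquired, ]
    out
}

#' Normalize k-space magnitude for training
#'
#' Scales data so that its maximum magnitude is 1 (when given the ACS block,
#' the recorded scale is the peak ACS magnitude); keeps the scale so the
#' operation is exactly invertible.
#'
#' @param k complex array (any shape), typically the ACS block.
#' @return list with \code{k} (normalized array) and \code{scale} (positive real).
#' @seealso [denormalizeKspace()]
#' @export
normalizeKspace <- function(k) {
    s <- max(abs(k))
    if (!is.finite(s) || s == 0) stop("cannot normalize all-zero k-space", call. = FALSE)
    list(k = k / s, scale = s)
}

#' Undo [normalizeKspace()]
#'
#' @param k normalized complex array.
#' @param scale the recorded normalization scale.
#' @return the denormalized array.
#' @export
denormalizeKspace <- function(k, scale) {
    stopifnot2(is.numeric(scale) && length(scale) == 1L && scale > 0,
               "scale must be a positive number")
    k * scale
}
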