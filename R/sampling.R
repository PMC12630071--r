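# Uniform retrospective undersampling with a centered fully sampled ACS block.
# All row indices follow the package convention: 0-based, half-open intervals.

#' Construct a uniform undersampling scheme
#'
#' The supported presets follow common cine protocols: R=4 with 26 ACS lines,
#' R=5 with 30, R=6 with 36; any valid combination is accepted.
#'
#' @param R integer acceleration rate (keep one of every R phase-encode lines).
#' @param nACS integer number of centered, fully sampled ACS lines.
#' @param ny integer phase-encode size.
#' @return a list of class \code{"SamplingScheme"}.
#' @export
samplingScheme <- function(R, nACS, ny) {
    R <- asInt(R, "R"); nACS <- asInt(nACS, "nACS"); ny <- asInt(ny, "ny")
    if (R < 1L) stop("R must be >= 1", call. = FALSE)
    if (nACS < 1L || nACS > ny) stop("nACS must be in [1, ny]", call. = FALSE)
    structure(list(R = R, nACS = nACS, ny = ny), class = "SamplingScheme")
}

#' Build the sampling mask of a scheme
#'
#' Acquired rows are the union of the lattice \code{\{r : r mod R == 0\}}
#' (0-based, lattice offset 0 so row 0 is always acquired) and the centered
#' ACS interval \code{[floor(ny/2) - floor(nACS/2), + nACS)}. The ACS is not
#' forced to align with the lattice; the two row sets are unioned.
#'
#' @param scheme a \code{SamplingScheme} from [samplingScheme()].
#' @return a \linkS4class{SamplingMask}.
#' @examples
#' m <- buildMask(samplingScheme(R = 4, nACS = 26, ny = 112))
#' sum(acquiredRows(m))  # 47 acquired lines
#' @export
buildMask <- function(scheme) {
    stopifnot2(inherits(scheme, "SamplingScheme"), "expected a SamplingScheme")
    ny <- scheme$ny; R <- scheme$R; nACS <- scheme$nACS
    if (R > 1L && nACS + R > ny)
        stop("ACS too large: need nACS + R <= ny for a nontrivial scheme", call. = FALSE)
    r0 <- seq_len(ny) - 1L
    acquired <- (r0 %% R) == 0L
    a0 <- ny %/% 2L - nACS %/% 2L
    a1 <- a0 + nACS
    acquired[(a0 + 1L):a1] <- TRUE
    new("SamplingMask", acquired = acquired, R = R, nACS = nACS,
        acsStart = as.integer(a0), acsEnd = as.integer(a1), latticeOffset = 0L)
}

#' @describeIn buildMask logical vector of acquired phase-encode rows.
#' @param mask a \linkS4class{SamplingMask}.
#' @export
acquiredRows <- function(mask) mask@acquired

#' @describeIn buildMask 0-based half-open ACS row interval \code{c(start, end)}.
#' @export
acsInterval <- function(mask) c(mask@acsStart, mask@acsEnd)

#' Retrospectively undersample a k-space frame
#'
#' Zeroes the phase-encode rows that the mask does not acquire; acquired rows
#' are passed through bit-identically.
#'
#' @param kspace complex array \code{[nCoils, ny, nx]}.
#' @param mask a \linkS4class{SamplingMask}.
#' @return complex array, same shape, zero on missing rows.
#' @export
undersample <- function(kspace, mask) {
    d <- frameDims(kspace)
    if (length(mask@acquired) != d[2])
        stop("mask ny does not match k-space phase-encode size", call. = FALSE)
    out <- kspace
    out[, !mask@acquired, ] <- 0i
    out
}

#' Extract the ACS block of a k-space frame
#'
#' @param kspace complex array \code{[nCoils, ny, nx]}.
#' @param mask a \linkS4class{SamplingMask}.
#' @return complex array \code{[nCoils, nACS, nx]}: the contiguous central
#'   fully sampled rows, untouched.
#' @export
extractACS <- function(kspace, mask) {
    d <- frameDims(kspace)
    if (length(mask@acquired) != d[2])
        stop("mask ny does not match k-space phase-encode size", call. = FALSE)
    rows <- (mask@acsStart + 1L):mask@acsEnd
    kspace[, rows, , drop = FALSE]
}

#' Write / read a mask as a 0/1 text column
#'
#' One line per phase-encode row, \code{1} = acquired.
#' @param mask a \linkS4class{SamplingMask}.
#' @param path file path.
#' @return \code{writeMaskText} returns \code{path} invisibly;
#'   \code{readMaskText} returns a logical vector.
#' @export
writeMaskText <- function(mask, path) {
    writeLines(as.character(as.integer(mask@acquired)), path)
    invisible(path)
}

#' @rdname writeMaskText
#' @export
readMaskText <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    as.logical(as.integer(readLines(path)))
}
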