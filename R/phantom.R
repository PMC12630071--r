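# Synthetic multi-slice, multi-phase, multi-coil cine phantom with known
# ground truth. The phantom emulates the two redundancy properties the
# weight-sharing strategies exploit: coil sensitivities are constant across
# cardiac phases (by construction) and drift smoothly across slices (coil
# ring rotation at rate sliceDrift).

#' Create a phantom configuration
#'
#' Defaults describe a modest short-axis cine stack: a static torso with
#' lungs and spine, a centrally placed heart disc whose radius completes one
#' smooth cycle over the cardiac phases, eight receive coils on a ring around
#' the body, a mild inter-slice drift, and a low level of complex Gaussian
#' k-space noise.
#'
#' @param ny,nx matrix size (>= 32 each).
#' @param nSlices,nPhases,nCoils stack geometry.
#' @param heartCenter (row, col) 0-based pixel coordinates; defaults to the
#'   image center.
#' @param heartRadiusRange (min, max) heart disc radius in pixels.
#' @param sliceDrift nonnegative drift rate: radians of coil-ring rotation
#'   (and proportional anatomy change) per slice away from the middle slice.
#' @param noiseStd complex-Gaussian std per k-space sample, relative to each
#'   frame's peak k-space magnitude.
#' @param coilBandlimit,objectBandlimit optional odd integers: confine the
#'   k-space support of the coil sensitivities / coil images to a centered
#'   square block (exact-recovery analyses); \code{NA} disables.
#' @param seed master seed for all phantom randomness.
#' @return a \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(ny = 96L, nx = 96L, nSlices = 3L, nPhases = 8L,
                          nCoils = 8L, heartCenter = c(ny %/% 2, nx %/% 2),
                          heartRadiusRange = c(0.09, 0.125) * min(ny, nx),
                          sliceDrift = 0.05, noiseStd = 0.001,
                          coilBandlimit = NA_integer_,
                          objectBandlimit = NA_integer_,
                          profileType = c("gaussian", "uniform", "harmonic"),
                          seed = 42L) {
    profileType <- match.arg(profileType)
    new("PhantomConfig",
        ny = asInt(ny, "ny"), nx = asInt(nx, "nx"),
        nSlices = asInt(nSlices, "nSlices"), nPhases = asInt(nPhases, "nPhases"),
        nCoils = asInt(nCoils, "nCoils"),
        heartCenter = as.numeric(heartCenter),
        heartRadiusRange = as.numeric(heartRadiusRange),
        sliceDrift = as.numeric(sliceDrift), noiseStd = as.numeric(noiseStd),
        coilBandlimit = as.integer(coilBandlimit),
        objectBandlimit = as.integer(objectBandlimit),
        profileType = profileType,
        seed = asInt(seed, "seed"))
}

# Project each [ny, nx] plane of a complex frame onto a centered b x b
# k-space block (b odd). Input and output are image-domain coil frames.
bandlimitFrame <- function(img, b) {
    d <- frameDims(img)
    k <- fft2c(img)
    keepY <- (d[2] %/% 2L) + seq.int(-(b %/% 2L), b %/% 2L) + 1L
    keepX <- (d[3] %/% 2L) + seq.int(-(b %/% 2L), b %/% 2L) + 1L
    kk <- array(0i, d)
    kk[, keepY, keepX] <- k[, keepY, keepX]
    ifft2c(kk)
}

#' Generate smooth complex coil sensitivity profiles for one slice
#'
#' Coils sit on a ring enclosing the field of view; each profile is a
#' Gaussian-apodized field with a smooth linear phase toward its coil and a
#' per-coil constant phase. Slice dependence is a rotation of the coil ring
#' by \code{sliceDrift * (sliceIndex - middle)} radians, so profiles drift
#' smoothly and monotonically with the drift rate. With
#' \code{profileType = "uniform"} all profiles are identically 1.
#'
#' @param nCoils number of coils (>= 1).
#' @param ny,nx matrix size.
#' @param sliceIndex 0-based slice index.
#' @param sliceDrift drift rate (radians/slice), >= 0.
#' @param bandlimit optional odd integer: after generation, each profile's
#'   centered 2-D FFT is truncated to the central \code{bandlimit} square
#'   block (exactly zero outside it).
#' @param seed integer seed (per-coil amplitude jitter stream).
#' @param nSlices total slices (defines the middle slice for the drift);
#'   default 1 treats \code{sliceIndex} relative to slice 0.
#' @param profileType \code{"gaussian"} (default), \code{"uniform"} (all
#'   profiles identically 1), or \code{"harmonic"} (each coil a single
#'   low-order complex exponential, giving constant sum-of-squares and
#'   k-space support of one bin per coil; the family used by exact-recovery
#'   analyses of linear k-space interpolation).
#' @return complex array \code{[nCoils, ny, nx]}.
#' @export
makeCoilSensitivities <- function(nCoils, ny, nx, sliceIndex = 0L, sliceDrift = 0,
                                  bandlimit = NULL, seed = 1L, nSlices = 1L,
                                  profileType = c("gaussian", "uniform", "harmonic")) {
    nCoils <- asInt(nCoils, "nCoils"); ny <- asInt(ny, "ny"); nx <- asInt(nx, "nx")
    profileType <- match.arg(profileType)
    if (nCoils < 1L) stop("nCoils must be >= 1", call. = FALSE)
    if (ny < 1L || nx < 1L) stop("dimensions must be positive", call. = FALSE)
    if (!is.null(bandlimit) && !is.na(bandlimit)) {
        bandlimit <- asInt(bandlimit, "bandlimit")
        if (bandlimit %% 2L == 0L || bandlimit > min(ny, nx))
            stop("bandlimit must be an odd integer <= min(ny, nx)", call. = FALSE)
    } else bandlimit <- NULL

    if (profileType == "uniform") {
        prof <- array(1 + 0i, c(nCoils, ny, nx))
        return(prof)
    }

    if (profileType == "harmonic") {
        # single low-order harmonic per coil, cycling through (u, v) pairs
        # that mix phase-encode orders 0 and 1 so coils always pair across
        # an odd ky offset; amplitudes jittered from the seeded stream
        freqs <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
                       c(0, -1), c(-1, 0), c(1, -1), c(-1, 1))
        amp <- withSeed(subSeed(seed, "coil-amp"),
                        1 + 0.3 * stats::runif(nCoils, -1, 1))
        yy <- matrix(seq_len(ny) - 1, ny, nx)
        xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
        prof <- array(0i, c(nCoils, ny, nx))
        for (cc in seq_len(nCoils)) {
            f <- freqs[(cc - 1L) %% nrow(freqs) + 1L, ]
            prof[cc, , ] <- amp[cc] *
                exp(2i * pi * (f[1] * yy / ny + f[2] * xx / nx)) *
                exp(1i * 2 * pi * cc / nCoils)
        }
        return(prof)
    }

    mid <- (nSlices - 1) / 2
    rot <- sliceDrift * (sliceIndex - mid)
    yy <- matrix(seq_len(ny) - 1 - (ny - 1) / 2, ny, nx)
    xx <- matrix(seq_len(nx) - 1 - (nx - 1) / 2, ny, nx, byrow = TRUE)
    # surface-coil-like falloff (SoS varies ~2x across the FOV) plus a
    # per-coil linear phase ramp; together they give the coil distinctness
    # needed to support 4- to 6-fold acceleration
    ringR <- 0.65 * max(ny, nx)
    sigma <- 0.35 * max(ny, nx)
    amp <- withSeed(subSeed(seed, "coil-amp"), 1 + 0.1 * stats::runif(nCoils, -1, 1))
    prof <- array(0i, c(nCoils, ny, nx))
    for (cc in seq_len(nCoils)) {
        th <- 2 * pi * (cc - 1) / nCoils + rot
        cy <- ringR * sin(th); cx <- ringR * cos(th)
        d2 <- (yy - cy)^2 + (xx - cx)^2
        mag <- amp[cc] * exp(-d2 / (2 * sigma^2))
        ph <- 1.5 * pi * (yy * sin(th) + xx * cos(th)) / max(ny, nx) + th / 3
        prof[cc, , ] <- mag * exp(1i * ph)
    }
    if (!is.null(bandlimit)) prof <- bandlimitFrame(prof, bandlimit)
    prof
}

# Static anatomy (real image) for one slice: superposed ellipses whose
# geometry drifts smoothly with the slice index, plus the heart disc whose
# radius follows one cosine cycle over the cardiac phases.
phantomAnatomy <- function(config, sliceIndex, phaseIndex) {
    ny <- config@ny; nx <- config@nx
    mid <- (config@nSlices - 1) / 2
    ds <- sliceIndex - mid
    g <- 1 + 0.015 * ds          # smooth anatomical scaling across slices
    yy <- matrix(seq_len(ny) - 1, ny, nx)
    xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
    cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
    ell <- function(y0, x0, a, b) ((yy - y0) / a)^2 + ((xx - x0) / b)^2 <= 1
    img <- matrix(0, ny, nx)
    img <- img + 0.8 * ell(cy, cx, 0.42 * ny * g, 0.46 * nx * g)       # torso
    img <- img - 0.45 * ell(cy - 0.05 * ny, cx - 0.24 * nx * g, 0.26 * ny, 0.14 * nx)
    img <- img - 0.45 * ell(cy - 0.05 * ny, cx + 0.24 * nx * g, 0.26 * ny, 0.14 * nx)
    img <- img + 0.4 * ell(cy + 0.33 * ny * g, cx, 0.06 * ny, 0.06 * nx)  # spine
    # smooth deterministic texture keeps calibration problems well conditioned
    img <- img + 0.05 * sin(2 * pi * 3 * yy / ny) * cos(2 * pi * 2 * xx / nx) *
        ell(cy, cx, 0.42 * ny * g, 0.46 * nx * g)
    r <- heartRadius(config, phaseIndex) * (1 - 0.02 * ds)
    disc <- (yy - config@heartCenter[1])^2 + (xx - config@heartCenter[2])^2 <= r^2
    img + 0.6 * disc
}

#' Heart disc radius at a cardiac phase
#'
#' \code{r(p) = rmin + (rmax - rmin) * (1 - cos(2 pi p / nPhases)) / 2}: one
#' full smooth contraction/relaxation cycle over the phases.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param phaseIndex 0-based phase index.
#' @return radius in pixels.
#' @export
heartRadius <- function(config, phaseIndex) {
    r <- config@heartRadiusRange
    r[1] + (r[2] - r[1]) * (1 - cos(2 * pi * phaseIndex / config@nPhases)) / 2
}

#' Rectangular region of interest around the heart
#'
#' A 70 x 70 pixel window centered on the configured heart center (the
#' conventional size for cine heart-region metrics), clipped to the image
#' bounds. Intervals are 0-based and half-open.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return a list with \code{row0}, \code{row1}, \code{col0}, \code{col1}
#'   (0-based half-open) of class \code{"HeartROI"}.
#' @examples
#' roi <- heartROI(phantomConfig(ny = 96, nx = 96, heartCenter = c(48, 48)))
#' c(roi$row0, roi$row1)  # 13 83
#' @export
heartROI <- function(config) {
    half <- 70L %/% 2L
    r0 <- max(0L, as.integer(floor(config@heartCenter[1])) - half)
    r1 <- min(config@ny, as.integer(floor(config@heartCenter[1])) + half)
    c0 <- max(0L, as.integer(floor(config@heartCenter[2])) - half)
    c1 <- min(config@nx, as.integer(floor(config@heartCenter[2])) + half)
    if (r1 <= r0 || c1 <= c0)
        stop("heart ROI does not fit in the image", call. = FALSE)
    structure(list(row0 = r0, row1 = r1, col0 = c0, col1 = c1), class = "HeartROI")
}

#' Generate a fully sampled synthetic cine stack with ground truth
#'
#' Builds, per slice, smooth complex coil sensitivities (constant across
#' phases, rotating across slices at the configured drift rate) and, per
#' phase, the anatomy image with the beating-heart disc; multiplies them into
#' coil images, transforms to k-space with the centered unitary FFT, and adds
#' independent complex Gaussian noise per k-space sample. The stored
#' \code{coilImages}/\code{sosImages} are noise-free ground truth.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return a \linkS4class{CineTruth}.
#' @export
generateCineTruth <- function(config) {
    stopifnot2(is(config, "PhantomConfig"), "expected a PhantomConfig")
    validObject(config)
    roi <- heartROI(config)
    ny <- config@ny; nx <- config@nx
    nS <- config@nSlices; nP <- config@nPhases; nC <- config@nCoils
    kd <- array(0i, c(nS, nP, nC, ny, nx))
    ci <- array(0i, c(nS, nP, nC, ny, nx))
    sos <- array(0, c(nS, nP, ny, nx))
    for (s in seq_len(nS)) {
        prof <- makeCoilSensitivities(nC, ny, nx, sliceIndex = s - 1L,
                                      sliceDrift = config@sliceDrift,
                                      bandlimit = if (is.na(config@coilBandlimit))
                                          NULL else config@coilBandlimit,
                                      seed = config@seed, nSlices = nS,
                                      profileType = config@profileType)
        for (p in seq_len(nP)) {
            anat <- phantomAnatomy(config, s - 1L, p - 1L)
            if (!is.na(config@objectBandlimit)) {
                # bandlimit the object itself (before coil weighting) so the
                # coil spectra keep the exact shift structure of the object
                a <- array(complex(real = anat), c(1L, ny, nx))
                anat <- matrix(bandlimitFrame(a, config@objectBandlimit)[1L, , ],
                               ny, nx)
            }
            frame <- array(0i, c(nC, ny, nx))
            for (cc in seq_len(nC)) frame[cc, , ] <- prof[cc, , ] * anat
            k <- fft2c(frame)
            if (config@noiseStd > 0) {
                sd1 <- config@noiseStd * max(abs(k)) / sqrt(2)
                noise <- withSeed(subSeed(config@seed, "noise", s, p), {
                    n <- length(k)
                    complex(real = stats::rnorm(n, 0, sd1),
                            imaginary = stats::rnorm(n, 0, sd1))
                })
                k <- k + array(noise, dim(k))
            }
            kd[s, p, , , ] <- k
            ci[s, p, , , ] <- frame
            sos[s, p, , ] <- sosCombine(frame)
        }
    }
    new("CineTruth", kspace = new("CineKSpace", kdata = kd),
        coilImages = ci, sosImages = sos,
        heartROI = unclass(roi), config = config)
}

#' Extract one [nCoils, ny, nx] k-space frame from a cine stack
#'
#' @param x a \linkS4class{CineKSpace} or \linkS4class{CineTruth}.
#' @param slice,phase 1-based slice and phase indices.
#' @return complex array \code{[nCoils, ny, nx]}.
#' @export
kspaceFrame <- function(x, slice, phase) {
    if (is(x, "CineTruth")) x <- x@kspace
    stopifnot2(is(x, "CineKSpace"), "expected a CineKSpace or CineTruth")
    d <- dim(x@kdata)
    array(x@kdata[slice, phase, , , ], d[3:5])
}

#' @describeIn kspaceFrame stack geometry accessors.
#' @export
nSlices <- function(x) dim(if (is(x, "CineTruth")) x@kspace@kdata else x@kdata)[1]

#' @rdname kspaceFrame
#' @export
nPhases <- function(x) dim(if (is(x, "CineTruth")) x@kspace@kdata else x@kdata)[2]

#' @rdname kspaceFrame
#' @export
nCoils <- function(x) dim(if (is(x, "CineTruth")) x@kspace@kdata else x@kdata)[3]
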