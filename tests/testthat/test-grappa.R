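# Calibration is validated against an exactly constructed linear model and
# the application operator against a brute-force per-pixel oracle.

# Build synthetic k-space where every missing line is an exact known linear
# combination (weights wStar) of its R-spaced acquired neighbors.
makeExactLinearKSpace <- function(nCoils = 3L, ny = 32L, nx = 16L, R = 2L,
                                  spec = grappaKernelSpec(R = R), seed = 4L) {
    set.seed(seed)
    k <- array(complex(real = rnorm(nCoils * ny * nx),
                       imaginary = rnorm(nCoils * ny * nx)), c(nCoils, ny, nx))
    nUnk <- nCoils * spec$nSourceLines * spec$kxTaps
    wStar <- lapply(seq_len(R - 1L), function(d)
        matrix(complex(real = rnorm(nUnk * nCoils, sd = 0.3),
                       imaginary = rnorm(nUnk * nCoils, sd = 0.3)), nUnk, nCoils))
    half <- spec$kxTaps %/% 2L
    # synthesize each non-lattice row from the acquired lattice rows
    for (m0 in seq.int(0L, ny - 1L)) {
        d <- m0 %% R
        if (d == 0L) next
        offs <- cineRAKI:::grappaSourceOffsets(spec, d)
        for (x in seq_len(nx)) {
            src <- complex(length.out = 0)
            for (ty in seq_along(offs)) {
                row <- m0 + offs[ty] + 1L
                for (tx in seq_len(spec$kxTaps)) {
                    cx <- x + tx - half - 1L
                    v <- if (row >= 1L && row <= ny && cx >= 1L && cx <= nx)
                        k[, row, cx] else rep(0i, nCoils)
                    src <- c(src, v)
                }
            }
            k[, m0 + 1L, x] <- as.vector(t(wStar[[d]]) %*% src)
        }
    }
    list(k = k, wStar = wStar, spec = spec)
}

test_that("calibration recovers an exactly realizable kernel", {
    R <- 2L
    ex <- makeExactLinearKSpace(nCoils = 3L, ny = 48L, nx = 24L, R = R)
    mask <- buildMask(samplingScheme(R, 30L, 48L))
    acs <- extractACS(ex$k, mask)
    # the synthetic relation holds at the application parity, so calibrate on
    # lattice-aligned windows
    w <- grappaCalibrate(acs, ex$spec, ridge = 0, acsStart = mask@acsStart)
    expect_lt(max(abs(w@weights[[1]] - ex$wStar[[1]])), 1e-8)

    # unknown count per offset: nCoils * nSourceLines * kxTaps
    expect_identical(nrow(w@weights[[1]]), 3L * 5L * 5L)
    expect_identical(ncol(w@weights[[1]]), 3L)
})

test_that("calibration rejects degenerate inputs", {
    mask <- buildMask(samplingScheme(2, 30, 48))
    zero <- array(0i, c(3, 30, 24))
    expect_error(grappaCalibrate(zero, grappaKernelSpec(R = 2)), "all-zero")

    small <- randomFrame(3, 6, 24)
    expect_error(grappaCalibrate(small, grappaKernelSpec(R = 2)), "infeasible")

    # duplicated coil -> rank deficient; ridge = 0 fails, ridge > 0 succeeds
    ex <- makeExactLinearKSpace(nCoils = 3L, ny = 48L, nx = 24L, R = 2L)
    dup <- ex$k[c(1, 1, 2, 3), , ]
    acs <- extractACS(dup, buildMask(samplingScheme(2, 30, 48)))
    expect_error(grappaCalibrate(acs, grappaKernelSpec(R = 2), ridge = 0),
                 "singular")
    wR <- grappaCalibrate(acs, grappaKernelSpec(R = 2), ridge = NULL)
    expect_true(all(is.finite(abs(wR@weights[[1]]))))
})

test_that("kernel application is linear, passthrough at R=1, and matches a
           brute-force per-pixel oracle bit-identically", {
    ex <- makeExactLinearKSpace(nCoils = 2L, ny = 32L, nx = 16L, R = 2L)
    mask <- buildMask(samplingScheme(2, 20, 32))
    acs <- extractACS(ex$k, mask)
    w <- grappaCalibrate(acs, ex$spec, ridge = 0)
    zf <- undersample(ex$k, mask)
    filled <- grappaApply(w, zf, mask)

    # linearity in the data
    a <- 2.5 - 1.25i
    expect_lt(max(abs(grappaApply(w, a * zf, mask) - a * filled)), 1e-9)

    # R = 1: identity
    m1 <- buildMask(samplingScheme(1, 8, 32))
    expect_identical(grappaApply(grappaCalibrate(acs, grappaKernelSpec(R = 1),
                                                 ridge = 0)
                     , ex$k, m1), ex$k)

    # brute-force per-pixel oracle, same accumulation order
    spec <- ex$spec
    half <- spec$kxTaps %/% 2L
    nC <- 2L; ny <- 32L; nx <- 16L
    lattice <- ((seq_len(ny) - 1L) %% 2L) == 0L
    latticeData <- zf; latticeData[, !lattice, ] <- 0i
    bf <- zf
    for (m in which(!acquiredRows(mask))) {
        m0 <- m - 1L
        d <- m0 %% 2L
        if (d == 0L) next
        offs <- cineRAKI:::grappaSourceOffsets(spec, d)
        for (x in seq_len(nx)) for (tc in seq_len(nC)) {
            acc <- 0i
            j <- 0L
            for (ty in seq_along(offs)) {
                row <- m0 + offs[ty] + 1L
                for (tx in seq_len(spec$kxTaps)) {
                    cx <- x + tx - half - 1L
                    for (cc in seq_len(nC)) {
                        j <- j + 1L
                        v <- if (row >= 1L && row <= ny && cx >= 1L && cx <= nx)
                            latticeData[cc, row, cx] else 0i
                        acc <- acc + v * w@weights[[d]][j, tc]
                    }
                }
            }
            bf[tc, m, x] <- acc
        }
    }
    expect_identical(filled, bf)
})

test_that("reconstruction is exact on the realizable harmonic phantom", {
    tr <- exactRecoveryTruth(ny = 32L, nCoils = 6L)
    f <- kspaceFrame(tr, 1, 1)
    mask <- buildMask(samplingScheme(2, 16, 32))
    ref <- matrix(tr@sosImages[1, 1, , ], 32, 32)

    acsPeak <- max(abs(extractACS(f, mask)))
    rec <- grappaReconstruct(f, mask, ridge = 1e-12 * acsPeak^2)
    expect_lt(nmse(ref, rec$image), 1e-6)
    expect_gt(psnr(ref, rec$image), 100)

    # fully sampled input: image equals the reference SoS exactly
    m1 <- buildMask(samplingScheme(1, 8, 32))
    rec1 <- grappaReconstruct(f, m1)
    expect_equal(rec1$image, ref, tolerance = 1e-12)
})

test_that("kernel application is shift-equivariant along the readout", {
    ex <- makeExactLinearKSpace(nCoils = 2L, ny = 32L, nx = 24L, R = 2L)
    mask <- buildMask(samplingScheme(2, 20, 32))
    acs <- extractACS(ex$k, mask)
    w <- grappaCalibrate(acs, ex$spec, ridge = 0)
    zf <- undersample(ex$k, mask)
    sh <- 5L
    zfs <- zf[, , c((sh + 1L):24L, 1:sh)]
    a <- grappaApply(w, zfs, mask)
    b <- grappaApply(w, zf, mask)[, , c((sh + 1L):24L, 1:sh)]
    # identical away from the kx boundary columns
    interior <- 4:16
    expect_lt(max(abs(a[, , interior] - b[, , interior])), 1e-9)
})
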