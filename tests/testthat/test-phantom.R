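test_that("coil sensitivity generation is reproducible and well-behaved", {
    p1 <- makeCoilSensitivities(4, 48, 48, sliceIndex = 1, sliceDrift = 0.1, seed = 5)
    p2 <- makeCoilSensitivities(4, 48, 48, sliceIndex = 1, sliceDrift = 0.1, seed = 5)
    expect_identical(p1, p2)

    # SoS strictly positive everywhere
    expect_true(all(sosCombine(p1) > 0))

    # uniform request: identically 1
    pu <- makeCoilSensitivities(1, 32, 32, profileType = "uniform")
    expect_true(all(pu == 1 + 0i))

    expect_error(makeCoilSensitivities(0, 32, 32), "nCoils")
    expect_error(makeCoilSensitivities(2, 32, 32, bandlimit = 4), "odd")
})

test_that("profile drift grows monotonically with the drift rate", {
    drifts <- c(0.02, 0.05, 0.1, 0.2)
    deltas <- vapply(drifts, function(dr) {
        a <- makeCoilSensitivities(6, 48, 48, sliceIndex = 0, sliceDrift = dr,
                                   seed = 5, nSlices = 3)
        b <- makeCoilSensitivities(6, 48, 48, sliceIndex = 1, sliceDrift = dr,
                                   seed = 5, nSlices = 3)
        mean(abs(a - b))
    }, numeric(1))
    expect_true(all(diff(deltas) > 0))
})

test_that("bandlimited profiles have k-space support confined to the block", {
    b <- 3L
    prof <- makeCoilSensitivities(4, 32, 32, bandlimit = b, seed = 2)
    k <- fft2c(prof)
    keep <- 16L + seq.int(-(b %/% 2L), b %/% 2L) + 1L
    outside <- k
    outside[, keep, keep] <- 0i
    expect_lt(sum(abs(outside)^2) / sum(abs(k)^2), 1e-10)
})

test_that("cine truth obeys its shape and Fourier contracts", {
    cfg <- phantomConfig(ny = 96, nx = 96, nSlices = 3, nPhases = 4, nCoils = 8,
                         seed = 1)
    tr <- generateCineTruth(cfg)
    expect_identical(dim(tr@kspace@kdata), c(3L, 4L, 8L, 96L, 96L))
    expect_identical(nSlices(tr), 3L)
    expect_identical(nPhases(tr), 4L)
    expect_identical(nCoils(tr), 8L)

    # noise-free: unitary IFFT of kspace reproduces the coil images
    cfg0 <- phantomConfig(ny = 64, nx = 64, nSlices = 1, nPhases = 2,
                          nCoils = 4, noiseStd = 0, seed = 1)
    tr0 <- generateCineTruth(cfg0)
    f <- kspaceFrame(tr0, 1, 2)
    ci <- array(tr0@coilImages[1, 2, , , ], c(4, 64, 64))
    expect_lt(max(abs(ifft2c(f) - ci)), 1e-10)
    # Parseval between the stored k-space and coil images
    expect_lt(abs(sum(abs(f)^2) - sum(abs(ci)^2)) / sum(abs(f)^2), 1e-8)
    # SoS consistency
    expect_equal(matrix(tr0@sosImages[1, 2, , ], 64, 64), sosCombine(ci))
})

test_that("only the heart disc moves between cardiac phases", {
    cfg <- phantomConfig(ny = 64, nx = 64, nSlices = 1, nPhases = 4, nCoils = 4,
                         noiseStd = 0, heartCenter = c(32, 32), seed = 1)
    tr <- generateCineTruth(cfg)
    d <- abs(tr@sosImages[1, 1, , ] - tr@sosImages[1, 3, , ])
    yy <- matrix(seq_len(64) - 1, 64, 64)
    xx <- t(yy)
    rmax <- max(cfg@heartRadiusRange) + 2
    insideDisc <- (yy - 32)^2 + (xx - 32)^2 <= rmax^2
    expect_true(all(d[!insideDisc] < 1e-12))
    expect_gt(max(d[insideDisc]), 0.1)

    # determinism of the full generator
    tr2 <- generateCineTruth(cfg)
    expect_identical(tr@kspace@kdata, tr2@kspace@kdata)
})

test_that("slice drift moves profiles away from the middle slice", {
    cfg <- phantomConfig(ny = 64, nx = 64, nSlices = 5, nPhases = 2, nCoils = 6,
                         noiseStd = 0, sliceDrift = 0.08, seed = 1)
    tr <- generateCineTruth(cfg)
    mid <- 3L
    dev <- vapply(1:5, function(s)
        mean(abs(tr@coilImages[s, 1, , , ] - tr@coilImages[mid, 1, , , ])),
        numeric(1))
    expect_true(all(diff(dev[mid:5]) > 0))
    expect_true(all(diff(dev[mid:1]) > 0))
})

test_that("the heart ROI is the clipped 70x70 window around the heart", {
    roi <- heartROI(phantomConfig(ny = 96, nx = 96, heartCenter = c(48, 48)))
    expect_identical(c(roi$row0, roi$row1, roi$col0, roi$col1),
                     c(13L, 83L, 13L, 83L))

    roiC <- heartROI(phantomConfig(ny = 96, nx = 96, heartCenter = c(10, 48)))
    expect_identical(c(roiC$row0, roiC$row1), c(0L, 45L))

    # area never exceeds 70 x 70
    for (c0 in list(c(5, 5), c(48, 90), c(90, 10))) {
        r <- heartROI(phantomConfig(ny = 96, nx = 96, heartCenter = c0))
        expect_lte((r$row1 - r$row0) * (r$col1 - r$col0), 70L * 70L)
    }
})
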