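test_that("network architectures match their reference parameter counts", {
    # 15-coil counts pin the hidden widths (64, 32) uniquely
    expect_identical(countParameters(buildNetwork("RAKI", 15)), 58814L)
    expect_identical(countParameters(buildNetwork("RRAKI", 15)), 81344L)
    expect_identical(countParameters(buildNetwork("SRAKI", 15)), 22530L)
    expect_identical(countParameters(buildNetwork("RRAKI", 15)),
                     countParameters(buildNetwork("RAKI", 15)) +
                     countParameters(buildNetwork("SRAKI", 15)))
    expect_identical(countParameters(buildNetwork("SRAKI", 1)), 102L)
    expect_error(buildNetwork("fancy", 4))

    s <- buildNetwork("SRAKI", 4)
    expect_identical(receptiveField(s), c(5L, 5L))
    r <- buildNetwork("RAKI", 4)
    expect_identical(receptiveField(r), c(7L, 7L))
    expect_identical(receptiveField(buildNetwork("RRAKI", 4)), c(7L, 7L))
    # channel contract: 2*nCoils in and out
    expect_identical(r@layers[[1]]$inCh, 8L)
    expect_identical(r@layers[[3]]$outCh, 8L)
})

test_that("training pairs zero off-lattice rows and expose the valid region", {
    cfg <- smallConfig(nCoils = 4L)
    tr <- generateCineTruth(cfg)
    mask <- buildMask(samplingScheme(4, 26, 64))
    zf <- undersample(kspaceFrame(tr, 1, 1), mask)
    acs <- extractACS(zf, mask)

    pair <- makeTrainingPair(acs, mask, rf = c(7L, 7L))
    expect_equal(pair$validRows, c(3, 23))
    expect_equal(pair$validCols, c(3, 61))

    # zeroed-row fraction ~ (R-1)/R up to lattice alignment
    rowZero <- apply(abs(pair$input), 2, sum) == 0
    expect_gt(mean(rowZero), 0.5)
    globalRows <- mask@acsStart + seq_len(26) - 1L
    expect_identical(which(!rowZero), which(globalRows %% 4L == 0L))

    # R = 1: input equals target
    m1 <- buildMask(samplingScheme(1, 26, 64))
    acs1 <- extractACS(kspaceFrame(tr, 1, 1), m1)
    p1 <- makeTrainingPair(acs1, m1, rf = c(5L, 5L))
    expect_identical(p1$input, p1$target)

    expect_error(makeTrainingPair(acs[, 1:5, ], mask, rf = c(7L, 7L)),
                 "infeasible")
})

test_that("training is deterministic and realizable optima are reached", {
    cfg <- smallConfig(nCoils = 4L)
    tr <- generateCineTruth(cfg)
    m1 <- buildMask(samplingScheme(1, 26, 64))
    acs <- extractACS(kspaceFrame(tr, 1, 1), m1)
    spec <- buildNetwork("SRAKI", 4)
    pair <- makeTrainingPair(acs, m1, rf = receptiveField(spec))

    # R = 1 pair: the identity kernel is in the model class
    ws <- trainNetwork(spec, pair, trainingHyper(seed = 2))
    expect_lt(finalLoss(ws), 1e-3)

    # bit-identical reruns under a fixed seed
    ws2 <- trainNetwork(spec, pair, trainingHyper(seed = 2))
    expect_identical(ws@params, ws2@params)
    expect_identical(ws@lossTrace, ws2@lossTrace)

    # running minimum of the loss trace is non-increasing
    expect_true(all(diff(cummin(ws@lossTrace)) <= 0))
})

test_that("the rRAKI combined loss is MAE(sum) + lambda * MAE(linear)", {
    cfg <- smallConfig(nCoils = 3L)
    tr <- generateCineTruth(cfg)
    mask <- buildMask(samplingScheme(4, 26, 64))
    acs <- extractACS(undersample(kspaceFrame(tr, 1, 1), mask), mask)
    spec <- buildNetwork("RRAKI", 3)
    pair <- makeTrainingPair(acs, mask, rf = receptiveField(spec))
    ws <- trainNetwork(spec, pair, trainingHyper(epochs = 30, seed = 4))
    comp <- networkLoss(ws, pair, lambda = 1)
    expect_equal(comp$total, comp$maeSum + comp$maeLinear)
    expect_equal(finalLoss(ws), comp$total, tolerance = 1e-10)
})

test_that("network application honors the identity kernel and linearity", {
    nC <- 3L
    spec <- buildNetwork("SRAKI", nC)
    # identity kernel: center tap 1 on the diagonal
    W <- matrix(0, 25 * 2 * nC, 2 * nC)
    for (ch in seq_len(2L * nC)) W[(ch - 1L) * 25L + 13L, ch] <- 1
    ws <- new("WeightSet", method = "SRAKI", spec = spec,
              params = list(list(W = W, b = numeric(2 * nC))),
              normScale = 1, provenance = list(slice = 1, phase = 1),
              lossTrace = 0)
    k <- randomFrame(nC, 32, 16)
    mask <- buildMask(samplingScheme(4, 12, 32))
    zf <- undersample(k, mask)
    out <- applyNetwork(ws, zf, mask)
    expect_lt(max(abs(out - zf)), 1e-12)
    expect_identical(dim(out), dim(zf))

    # linearity of the bias-free linear path before data consistency
    a <- 3
    p1 <- applyNetwork(ws, zf, mask, dc = FALSE)
    p2 <- applyNetwork(ws, a * zf, mask, dc = FALSE)
    expect_lt(max(abs(p2 - a * p1)), 1e-9)

    expect_error(applyNetwork(ws, randomFrame(2, 32, 16), mask), "coil")
})

test_that("SRAKI clearly beats zero-filling with bandlimited sensitivities", {
    cfg <- phantomConfig(ny = 64, nx = 64, nSlices = 1, nPhases = 1,
                         nCoils = 8, noiseStd = 0, coilBandlimit = 7L,
                         seed = 11)
    tr <- generateCineTruth(cfg)
    f <- kspaceFrame(tr, 1, 1)
    mask <- buildMask(samplingScheme(2, 16, 64))
    zf <- undersample(f, mask)
    spec <- buildNetwork("SRAKI", 8)
    pair <- makeTrainingPair(extractACS(zf, mask), mask,
                             rf = receptiveField(spec))
    ws <- trainNetwork(spec, pair, trainingHyper(seed = 6))
    ref <- matrix(tr@sosImages[1, 1, , ], 64, 64)
    rec <- sosCombine(ifft2c(applyNetwork(ws, zf, mask)))
    zfi <- sosCombine(ifft2c(zf))
    expect_gte(psnr(ref, rec) - psnr(ref, zfi), 10)
})
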