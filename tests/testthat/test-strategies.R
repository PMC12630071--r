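test_that("plans contain the advertised training counts and cover all frames", {
    expect_length(makePlan(9, 23, strategySpec("per_frame")), 207L)
    expect_length(makePlan(9, 23, strategySpec("mp")), 9L)
    expect_length(makePlan(9, 23, strategySpec("mp_ms", groupSize = 3)), 3L)

    for (nm in c("per_frame", "mp", "mp_ms")) {
        pl <- makePlan(9, 5, strategySpec(nm, groupSize = 3, seed = 2))
        expect_true(checkPlanCoverage(pl, 9, 5))
    }
    pl <- makePlan(7, 4, strategySpec("ms", groupSize = 3))
    expect_true(checkPlanCoverage(pl, 7, 4))

    expect_error(makePlan(2, 4, strategySpec("ms", groupSize = 5)), "exceeds")
})

test_that("the proposed grouping trains the middle slice of each triplet", {
    pl <- makePlan(9, 23, strategySpec("mp_ms", groupSize = 3,
                                       phaseSelection = "fixed"))
    trained <- vapply(pl, function(e) e$train$slices, integer(1))
    expect_identical(trained, c(2L, 5L, 8L))   # 1-based middles of {1:3},{4:6},{7:9}
    covered <- lapply(pl, function(e) sort(unique(e$covers$slice)))
    expect_identical(covered, list(1:3, 4:6, 7:9))
})

test_that("multi-slice ablation plans have the canonical geometry", {
    v <- msVariants(9, nPhases = 4)
    expect_named(v, c("1/1", "9/9", "1/9", "1/5", "1/3"))
    # (1/1): one training per frame and phase
    expect_length(v[["1/1"]], 36L)
    # (9/9): a single joint model per phase
    expect_length(v[["9/9"]], 4L)
    expect_identical(v[["9/9"]][[1]]$train$slices, 1:9)
    # (1/9): middle slice (1-based 5) trained at every phase
    expect_length(v[["1/9"]], 4L)
    expect_true(all(vapply(v[["1/9"]], function(e) e$train$slices, integer(1)) == 5L))
    # (1/5): trained-slice set {3, 7} (1-based), groups 1:5 and 6:9
    t15 <- unique(vapply(v[["1/5"]], function(e) e$train$slices, integer(1)))
    expect_identical(sort(t15), c(3L, 7L))
    g2 <- v[["1/5"]][[5]]$covers
    expect_identical(sort(unique(g2$slice)), 6:9)
    for (nm in names(v)) expect_true(checkPlanCoverage(v[[nm]], 9, 4))
    expect_error(msVariants(7, 4), "9 slices")
})

test_that("random phase selection is seeded and fixed mode hits the middle", {
    a <- makePlan(5, 9, strategySpec("mp", seed = 3))
    b <- makePlan(5, 9, strategySpec("mp", seed = 3))
    expect_identical(a, b)
    fx <- makePlan(5, 9, strategySpec("mp", phaseSelection = "fixed"))
    expect_true(all(vapply(fx, function(e) e$train$phase, integer(1)) == 5L))
})

test_that("strategy runs cover the stack and record timing per frame", {
    cfg <- phantomConfig(ny = 64, nx = 64, nSlices = 2, nPhases = 2,
                         nCoils = 4, seed = 2)
    tr <- generateCineTruth(cfg)
    mask <- buildMask(samplingScheme(4, 26, 64))
    hyper <- trainingHyper(epochs = 10, seed = 5)

    res <- runStrategy(tr, mask, "sraki", strategySpec("mp_ms", groupSize = 1,
                                                       phaseSelection = "fixed"),
                       hyper)
    expect_s4_class(res, "ReconResult")
    expect_identical(dim(res@images), c(2L, 2L, 64L, 64L))
    expect_identical(nrow(res@timing), 4L)
    expect_true(all(res@images >= 0))
    expect_true(all(unlist(res@timing[, 3:6]) >= 0))
    expect_length(res@weights, 2L)

    # GRAPPA path runs on the same plans
    resG <- runStrategy(tr, mask, "grappa", strategySpec("per_frame"))
    expect_identical(dim(resG@images), dim(res@images))
    expect_length(resG@weights, 4L)
    expect_s4_class(resG@weights[[1]], "GrappaWeights")
})

test_that("reruns with the same seed are bit-identical", {
    cfg <- phantomConfig(ny = 64, nx = 64, nSlices = 1, nPhases = 2,
                         nCoils = 4, seed = 2)
    tr <- generateCineTruth(cfg)
    mask <- buildMask(samplingScheme(4, 26, 64))
    hyper <- trainingHyper(epochs = 15, seed = 11)
    s <- strategySpec("mp", seed = 11)
    r1 <- runStrategy(tr, mask, "sraki", s, hyper)
    r2 <- runStrategy(tr, mask, "sraki", s, hyper)
    expect_identical(r1@images, r2@images)
})
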