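# Shared fixtures: small phantoms and masks built in code at test time.

smallConfig <- function(...) {
    args <- list(ny = 64L, nx = 64L, nSlices = 1L, nPhases = 1L, nCoils = 8L,
                 seed = 3L)
    args[names(list(...))] <- list(...)
    do.call(phantomConfig, args)
}

# noise-free instance on which a linear interpolation kernel is exactly
# realizable at R = 2 (single-harmonic constant-SoS coils, bandlimited object)
exactRecoveryTruth <- function(ny = 32L, nCoils = 6L, noiseStd = 0, seed = 11L) {
    generateCineTruth(phantomConfig(
        ny = ny, nx = ny, nSlices = 1L, nPhases = 1L, nCoils = nCoils,
        noiseStd = noiseStd, heartCenter = c(ny %/% 2, ny %/% 2),
        heartRadiusRange = c(4, 6), profileType = "harmonic",
        objectBandlimit = as.integer(2L * (ny %/% 3L) + 1L), seed = seed))
}

randomFrame <- function(nCoils = 3L, ny = 16L, nx = 16L, seed = 1L) {
    set.seed(seed)
    array(complex(real = rnorm(nCoils * ny * nx),
                  imaginary = rnorm(nCoils * ny * nx)), c(nCoils, ny, nx))
}
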