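# Scan-specific k-space interpolation networks trained on the ACS:
#   SRAKI — one linear 5x5 convolution (2N -> 2N channels, bias, no activation);
#   RAKI  — conv 2N->64 (5x5) + ReLU, conv 64->32 (1x1) + ReLU, conv 32->2N (3x3);
#   rRAKI — the RAKI path plus a parallel SRAKI-style linear path, output = sum,
#           trained with MAE(sum, target) + lambda * MAE(linear, target).
#
# Convolutions are dense ("same"-padded, undilated) on the zero-filled
# channel grid and predict all 2N channels of the complete k-space; training
# is full-batch gradient descent (Adam) on the single ACS tensor with the
# loss masked to the interior region unaffected by zero padding.
#
# The engine represents feature maps as [ny*nx, channels] matrices
# (column-major pixels) and implements convolution as im2col + matrix
# multiply, with the exact adjoint (col2im scatter-add) for backpropagation.

layerSpec <- function(inCh, outCh, ky, kx, activation = "none") {
    list(inCh = as.integer(inCh), outCh = as.integer(outCh),
         ky = as.integer(ky), kx = as.integer(kx), bias = TRUE,
         activation = activation)
}

#' Build a scan-specific network architecture
#'
#' @param method \code{"SRAKI"}, \code{"RAKI"} or \code{"RRAKI"}.
#' @param nCoils coil count; the network maps \code{2*nCoils} real channels
#'   (real and imaginary parts) to the same number.
#' @return a \linkS4class{NetworkSpec}.
#' @examples
#' countParameters(buildNetwork("SRAKI", 15))  # 22530
#' countParameters(buildNetwork("RAKI", 15))   # 58814
#' countParameters(buildNetwork("RRAKI", 15))  # 81344
#' @export
buildNetwork <- function(method = c("SRAKI", "RAKI", "RRAKI"), nCoils) {
    method <- match.arg(toupper(method), c("SRAKI", "RAKI", "RRAKI"))
    nCoils <- asInt(nCoils, "nCoils")
    if (nCoils < 1L) stop("nCoils must be >= 1", call. = FALSE)
    n2 <- 2L * nCoils
    layers <- switch(method,
        SRAKI = list(layerSpec(n2, n2, 5L, 5L)),
        RAKI = list(layerSpec(n2, 64L, 5L, 5L, "relu"),
                    layerSpec(64L, 32L, 1L, 1L, "relu"),
                    layerSpec(32L, n2, 3L, 3L)),
        RRAKI = list(layerSpec(n2, 64L, 5L, 5L, "relu"),
                     layerSpec(64L, 32L, 1L, 1L, "relu"),
                     layerSpec(32L, n2, 3L, 3L)))
    lin <- if (method == "RRAKI") layerSpec(n2, n2, 5L, 5L) else list()
    new("NetworkSpec", method = method, layers = layers, linearPath = lin,
        nCoils = nCoils)
}

#' Count trainable parameters of a network
#'
#' Sum over layers (both paths for rRAKI) of
#' \code{inCh * outCh * ky * kx + outCh}.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return integer parameter count.
#' @export
countParameters <- function(spec) {
    stopifnot2(is(spec, "NetworkSpec"), "expected a NetworkSpec")
    cnt <- function(l) l$inCh * l$outCh * l$ky * l$kx + l$outCh
    tot <- sum(vapply(spec@layers, cnt, numeric(1)))
    if (length(spec@linearPath)) tot <- tot + cnt(spec@linearPath)
    as.integer(tot)
}

#' Receptive-field extent of a network
#'
#' \code{1 + sum(k - 1)} over the serial layers, per dimension; rRAKI takes
#' the larger of its two paths.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return integer vector \code{c(ky, kx)}.
#' @export
receptiveField <- function(spec) {
    rf <- function(ls, f) 1L + sum(vapply(ls, function(l) l[[f]] - 1L, integer(1)))
    ky <- rf(spec@layers, "ky"); kx <- rf(spec@layers, "kx")
    if (length(spec@linearPath)) {
        ky <- max(ky, spec@linearPath$ky)
        kx <- max(kx, spec@linearPath$kx)
    }
    c(ky, kx)
}

# ---- im2col convolution engine -------------------------------------------

# Precompute the gather index: for an [ny, nx] plane zero-padded to
# [ny+ky-1, nx+kx-1], idx[pos, tap] is the padded linear index feeding output
# position pos for tap (dy, dx) (dy fastest). Within a fixed tap column the
# indices are distinct, so the adjoint scatter per tap needs no deduplication.
im2colIndex <- function(ny, nx, ky, kx) {
    nyp <- ny + ky - 1L
    py <- rep.int(seq_len(ny), nx)
    px <- rep(seq_len(nx), each = ny)
    idx <- matrix(0L, ny * nx, ky * kx)
    t <- 0L
    for (dx in seq_len(kx)) for (dy in seq_len(ky)) {
        t <- t + 1L
        idx[, t] <- (px + dx - 2L) * nyp + (py + dy - 1L)
    }
    idx
}

padChannel <- function(v, ny, nx, ky, kx) {
    nyp <- ny + ky - 1L; nxp <- nx + kx - 1L
    xp <- matrix(0, nyp, nxp)
    xp[(ky %/% 2L) + seq_len(ny), (kx %/% 2L) + seq_len(nx)] <- v
    xp
}

# x: [ny*nx, C] -> [ny*nx, ky*kx*C], channel-major blocks of ky*kx taps.
im2col <- function(x, ny, nx, ky, kx, idx) {
    C <- ncol(x)
    kk <- ky * kx
    out <- matrix(0, ny * nx, kk * C)
    for (cc in seq_len(C)) {
        xp <- padChannel(matrix(x[, cc], ny, nx), ny, nx, ky, kx)
        out[, (cc - 1L) * kk + seq_len(kk)] <- xp[idx]
    }
    out
}

# Adjoint of im2col: scatter-add gradient columns back to [ny*nx, C].
col2im <- function(g, ny, nx, ky, kx, idx) {
    C <- ncol(g) / (ky * kx)
    kk <- ky * kx
    nyp <- ny + ky - 1L; nxp <- nx + kx - 1L
    out <- matrix(0, ny * nx, C)
    ys <- (ky %/% 2L) + seq_len(ny); xs <- (kx %/% 2L) + seq_len(nx)
    for (cc in seq_len(C)) {
        acc <- matrix(0, nyp, nxp)
        for (t in seq_len(kk)) {
            col <- g[, (cc - 1L) * kk + t]
            acc[idx[, t]] <- acc[idx[, t]] + col
        }
        out[, cc] <- acc[ys, xs]
    }
    out
}

# Forward pass through a serial layer list. Returns list(out, cache).
convForward <- function(layers, x, ny, nx, params, idxCache) {
    cache <- vector("list", length(layers))
    h <- x
    for (i in seq_along(layers)) {
        l <- layers[[i]]
        key <- paste(l$ky, l$kx)
        idx <- idxCache[[key]]
        xc <- if (l$ky == 1L && l$kx == 1L) h else im2col(h, ny, nx, l$ky, l$kx, idx)
        z <- xc %*% params[[i]]$W
        z <- sweep(z, 2L, params[[i]]$b, "+")
        a <- if (identical(l$activation, "relu")) z * (z > 0) else z
        cache[[i]] <- list(xc = xc, z = z)
        h <- a
    }
    list(out = h, cache = cache)
}

# Backward pass: dOut is the gradient wrt the serial output. Returns
# list(grads = per-layer list(W, b)).
convBackward <- function(layers, dOut, ny, nx, params, cache, idxCache) {
    grads <- vector("list", length(layers))
    g <- dOut
    for (i in rev(seq_along(layers))) {
        l <- layers[[i]]
        if (identical(l$activation, "relu")) g <- g * (cache[[i]]$z > 0)
        grads[[i]] <- list(W = crossprod(cache[[i]]$xc, g), b = colSums(g))
        if (i > 1L) {
            gx <- g %*% t(params[[i]]$W)
            g <- if (l$ky == 1L && l$kx == 1L) gx
                 else col2im(gx, ny, nx, l$ky, l$kx, idxCache[[paste(l$ky, l$kx)]])
        }
    }
    grads
}

initParams <- function(layers, seed) {
    withSeed(seed, lapply(layers, function(l) {
        fanIn <- l$ky * l$kx * l$inCh
        bound <- 1 / sqrt(fanIn)
        list(W = matrix(stats::runif(fanIn * l$outCh, -bound, bound), fanIn, l$outCh),
             b = numeric(l$outCh))
    }))
}

idxCacheFor <- function(spec, ny, nx) {
    ls <- spec@layers
    if (length(spec@linearPath)) ls <- c(ls, list(spec@linearPath))
    cache <- list()
    for (l in ls) {
        key <- paste(l$ky, l$kx)
        if (is.null(cache[[key]]))
            cache[[key]] <- im2colIndex(ny, nx, l$ky, l$kx)
    }
    cache
}

# ---- training -------------------------------------------------------------

#' Training hyperparameters
#'
#' Defaults: MAE loss, 600 epochs of full-batch Adam at lr 0.01 with a
#' reduce-on-plateau schedule (factor 0.1, patience 10, relative improvement
#' threshold 0.001) monitoring the training loss; the rRAKI combination
#' weight is \code{lambda = 1}.
#'
#' @param epochs,lr,factor,patience,threshold,lambda,seed see description.
#' @return list of class \code{"TrainingHyper"}.
#' @export
trainingHyper <- function(epochs = 600L, lr = 0.01, factor = 0.1, patience = 10L,
                          threshold = 0.001, lambda = 1, seed = 1L) {
    stopifnot2(epochs >= 1L, "epochs must be >= 1")
    stopifnot2(lr > 0, "lr must be positive")
    stopifnot2(lambda >= 0, "lambda must be >= 0")
    structure(list(epochs = as.integer(epochs), lr = lr, factor = factor,
                   patience = as.integer(patience), threshold = threshold,
                   lambda = lambda, seed = asInt(seed, "seed")),
              class = "TrainingHyper")
}

#' Build the (input, target) training pair from an ACS block
#'
#' The input is the ACS with rows off the global acquired lattice zeroed
#' (retrospective undersampling restricted to the ACS block); the target is
#' the full ACS. Both are scaled by the normalization record and packed as
#' real channel stacks. The valid region excludes a border of half the
#' receptive field on each side so padded convolutions never contribute to
#' the loss.
#'
#' @param acs complex array \code{[nCoils, nACS, nx]}.
#' @param mask the \linkS4class{SamplingMask} (locates the ACS on the global
#'   lattice).
#' @param norm normalization record from [normalizeKspace()] (list with
#'   \code{scale}), or \code{NULL} to compute it from the ACS.
#' @param rf receptive field \code{c(ky, kx)} of the network to be trained.
#' @return list with \code{input}, \code{target} (\code{[2*nCoils, nACS, nx]}
#'   real arrays), \code{validRows}, \code{validCols} (0-based half-open),
#'   and \code{scale}.
#' @export
makeTrainingPair <- function(acs, mask, norm = NULL, rf = c(5L, 5L)) {
    d <- frameDims(acs)
    nACS <- d[2]; nx <- d[3]
    if (length(rf) == 1L) rf <- c(rf, rf)
    my <- rf[1] %/% 2L; mx <- rf[2] %/% 2L
    if (nACS <= rf[1])
        stop("training infeasible: ACS shorter than the receptive field", call. = FALSE)
    if (is.null(norm)) norm <- normalizeKspace(acs)
    scale <- norm$scale
    acsN <- acs / scale
    globalRows <- mask@acsStart + seq_len(nACS) - 1L     # 0-based
    onLattice <- ((globalRows - mask@latticeOffset) %% mask@R) == 0L
    input <- acsN
    input[, !onLattice, ] <- 0i
    list(input = splitComplex(input), target = splitComplex(acsN),
         validRows = c(my, nACS - my), validCols = c(mx, nx - mx),
         scale = scale)
}

adamInit <- function(params) lapply(params, function(p)
    list(mW = 0 * p$W, vW = 0 * p$W, mb = 0 * p$b, vb = 0 * p$b))

adamStep <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
    for (i in seq_along(params)) {
        st <- state[[i]]; g <- grads[[i]]
        st$mW <- beta1 * st$mW + (1 - beta1) * g$W
        st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
        st$mb <- beta1 * st$mb + (1 - beta1) * g$b
        st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
        mhatW <- st$mW / (1 - beta1^t); vhatW <- st$vW / (1 - beta2^t)
        mhatb <- st$mb / (1 - beta1^t); vhatb <- st$vb / (1 - beta2^t)
        params[[i]]$W <- params[[i]]$W - lr * mhatW / (sqrt(vhatW) + eps)
        params[[i]]$b <- params[[i]]$b - lr * mhatb / (sqrt(vhatb) + eps)
        state[[i]] <- st
    }
    list(params = params, state = state)
}

# Channel-matrix [npix, C] view of a [C, ny, nx] stack.
chanMatrix <- function(x) {
    d <- dim(x)
    t(matrix(x, d[1], d[2] * d[3]))
}
unchanMatrix <- function(m, C, ny, nx) array(t(m), c(C, ny, nx))

validMaskVector <- function(ny, nx, validRows, validCols) {
    py <- rep.int(seq_len(ny) - 1L, nx)
    px <- rep(seq_len(nx) - 1L, each = ny)
    py >= validRows[1] & py < validRows[2] & px >= validCols[1] & px < validCols[2]
}

#' Train a scan-specific network on one or more ACS pairs
#'
#' Full-batch Adam on the mean-absolute-error between prediction and target
#' over the valid region (rRAKI: \code{MAE(sum path, target) + lambda *
#' MAE(linear path, target)}); with several pairs (joint multi-slice models)
#' gradients are averaged over the pairs. Deterministic for a fixed
#' \code{hyper$seed}.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param pair a pair from [makeTrainingPair()], or a list of such pairs.
#' @param hyper a \code{TrainingHyper}.
#' @param provenance optional list tagging the trained (slice, phase).
#' @return a \linkS4class{WeightSet} (the per-epoch loss trace is in
#'   \code{@lossTrace}).
#' @export
trainNetwork <- function(spec, pair, hyper = trainingHyper(),
                         provenance = list()) {
    stopifnot2(is(spec, "NetworkSpec"), "expected a NetworkSpec")
    pairs <- if (!is.null(pair$input)) list(pair) else pair
    stopifnot2(length(pairs) >= 1L, "no training pairs")
    d1 <- dim(pairs[[1]]$input)
    ny <- d1[2]; nx <- d1[3]; C <- d1[1]
    stopifnot2(C == 2L * spec@nCoils, "pair channel count does not match spec")
    idxCache <- idxCacheFor(spec, ny, nx)
    hasLin <- length(spec@linearPath) > 0L

    prep <- lapply(pairs, function(p) {
        stopifnot2(all(dim(p$input) == d1), "all pairs must share a shape")
        x <- chanMatrix(p$input)
        y <- chanMatrix(p$target)
        vm <- validMaskVector(ny, nx, p$validRows, p$validCols)
        l1 <- spec@layers[[1]]
        xc1 <- if (l1$ky == 1L && l1$kx == 1L) x
               else im2col(x, ny, nx, l1$ky, l1$kx, idxCache[[paste(l1$ky, l1$kx)]])
        xcl <- if (hasLin)
            im2col(x, ny, nx, spec@linearPath$ky, spec@linearPath$kx,
                   idxCache[[paste(spec@linearPath$ky, spec@linearPath$kx)]])
        else NULL
        list(x = x, y = y, vm = vm, xc1 = xc1, xcl = xcl, nValid = sum(vm) * ncol(y))
    })

    params <- initParams(spec@layers, subSeed(hyper$seed, "init", spec@method))
    if (hasLin)
        linParams <- initParams(list(spec@linearPath),
                                subSeed(hyper$seed, "init-linear", spec@method))

    state <- adamInit(params)
    if (hasLin) linState <- adamInit(linParams)
    lr <- hyper$lr
    best <- Inf; bad <- 0L
    lossTrace <- numeric(hyper$epochs)

    for (ep in seq_len(hyper$epochs)) {
        totLoss <- 0
        gAcc <- NULL; gLinAcc <- NULL
        for (pp in prep) {
            fw <- convForwardCached(spec@layers, pp$xc1, pp$x, ny, nx, params, idxCache)
            out <- fw$out
            if (hasLin) {
                zlin <- sweep(pp$xcl %*% linParams[[1]]$W, 2L, linParams[[1]]$b, "+")
                total <- out + zlin
                rSum <- total - pp$y
                rLin <- zlin - pp$y
                rSum[!pp$vm, ] <- 0; rLin[!pp$vm, ] <- 0
                loss <- sum(abs(rSum)) / pp$nValid +
                    hyper$lambda * sum(abs(rLin)) / pp$nValid
                dSum <- sign(rSum) / pp$nValid
                dLin <- dSum + hyper$lambda * sign(rLin) / pp$nValid
                g <- convBackward(spec@layers, dSum, ny, nx, params, fw$cache, idxCache)
                gLin <- list(list(W = crossprod(pp$xcl, dLin), b = colSums(dLin)))
            } else {
                r <- out - pp$y
                r[!pp$vm, ] <- 0
                loss <- sum(abs(r)) / pp$nValid
                dOut <- sign(r) / pp$nValid
                g <- convBackward(spec@layers, dOut, ny, nx, params, fw$cache, idxCache)
                gLin <- NULL
            }
            totLoss <- totLoss + loss
            gAcc <- accumGrads(gAcc, g)
            if (hasLin) gLinAcc <- accumGrads(gLinAcc, gLin)
        }
        np <- length(prep)
        totLoss <- totLoss / np
        if (!is.finite(totLoss))
            stop(sprintf("training diverged (non-finite loss at epoch %d)", ep),
                 call. = FALSE)
        gAcc <- scaleGrads(gAcc, 1 / np)
        if (hasLin) gLinAcc <- scaleGrads(gLinAcc, 1 / np)
        upd <- adamStep(params, gAcc, state, lr, ep)
        params <- upd$params; state <- upd$state
        if (hasLin) {
            updL <- adamStep(linParams, gLinAcc, linState, lr, ep)
            linParams <- updL$params; linState <- updL$state
        }
        lossTrace[ep] <- totLoss
        # reduce-on-plateau, relative threshold semantics
        if (totLoss < best * (1 - hyper$threshold)) {
            best <- totLoss; bad <- 0L
        } else {
            bad <- bad + 1L
            if (bad > hyper$patience) {
                lr <- lr * hyper$factor
                bad <- 0L
            }
        }
    }

    # evaluate the loss once more at the returned weights so finalLoss()
    # reports the loss of the weights actually handed back
    finLoss <- 0
    for (pp in prep) {
        fw <- convForwardCached(spec@layers, pp$xc1, pp$x, ny, nx, params, idxCache)
        if (hasLin) {
            zlin <- sweep(pp$xcl %*% linParams[[1]]$W, 2L, linParams[[1]]$b, "+")
            rSum <- fw$out + zlin - pp$y; rLin <- zlin - pp$y
            rSum[!pp$vm, ] <- 0; rLin[!pp$vm, ] <- 0
            finLoss <- finLoss + sum(abs(rSum)) / pp$nValid +
                hyper$lambda * sum(abs(rLin)) / pp$nValid
        } else {
            r <- fw$out - pp$y
            r[!pp$vm, ] <- 0
            finLoss <- finLoss + sum(abs(r)) / pp$nValid
        }
    }
    lossTrace <- c(lossTrace, finLoss / length(prep))

    allParams <- params
    if (hasLin) allParams$linear <- linParams[[1]]
    new("WeightSet", method = spec@method, spec = spec, params = allParams,
        normScale = pairs[[1]]$scale,
        provenance = provenance, lossTrace = lossTrace)
}

# Forward pass that reuses the precomputed first-layer im2col (the input is
# constant across epochs in full-batch training).
convForwardCached <- function(layers, xc1, x, ny, nx, params, idxCache) {
    cache <- vector("list", length(layers))
    h <- NULL
    for (i in seq_along(layers)) {
        l <- layers[[i]]
        xc <- if (i == 1L) xc1
              else if (l$ky == 1L && l$kx == 1L) h
              else im2col(h, ny, nx, l$ky, l$kx, idxCache[[paste(l$ky, l$kx)]])
        z <- sweep(xc %*% params[[i]]$W, 2L, params[[i]]$b, "+")
        a <- if (identical(l$activation, "relu")) z * (z > 0) else z
        cache[[i]] <- list(xc = xc, z = z)
        h <- a
    }
    list(out = h, cache = cache)
}

accumGrads <- function(acc, g) {
    if (is.null(acc)) return(g)
    for (i in seq_along(g)) {
        acc[[i]]$W <- acc[[i]]$W + g[[i]]$W
        acc[[i]]$b <- acc[[i]]$b + g[[i]]$b
    }
    acc
}
scaleGrads <- function(g, f) {
    for (i in seq_along(g)) {
        g[[i]]$W <- g[[i]]$W * f
        g[[i]]$b <- g[[i]]$b * f
    }
    g
}

#' Final training loss of a weight set
#' @param ws a \linkS4class{WeightSet}.
#' @return last entry of the loss trace (evaluated at the returned weights).
#' @export
finalLoss <- function(ws) utils::tail(ws@lossTrace, 1L)

#' Evaluate the training loss of a weight set on a pair
#'
#' Recomputes the masked mean-absolute-error components at the stored
#' weights: for rRAKI returns \code{total} (= MAE(sum) + lambda * MAE(linear)),
#' \code{maeSum} and \code{maeLinear}; otherwise \code{total} = MAE.
#'
#' @param ws a \linkS4class{WeightSet}.
#' @param pair a pair from [makeTrainingPair()].
#' @param lambda rRAKI combination weight (default 1).
#' @return named list of loss components.
#' @export
networkLoss <- function(ws, pair, lambda = 1) {
    spec <- ws@spec
    d1 <- dim(pair$input)
    ny <- d1[2]; nx <- d1[3]
    idxCache <- idxCacheFor(spec, ny, nx)
    x <- chanMatrix(pair$input); y <- chanMatrix(pair$target)
    vm <- validMaskVector(ny, nx, pair$validRows, pair$validCols)
    nValid <- sum(vm) * ncol(y)
    params <- ws@params[seq_along(spec@layers)]
    out <- convForward(spec@layers, x, ny, nx, params, idxCache)$out
    if (length(spec@linearPath)) {
        l <- spec@linearPath
        xc <- im2col(x, ny, nx, l$ky, l$kx, idxCache[[paste(l$ky, l$kx)]])
        zlin <- sweep(xc %*% ws@params$linear$W, 2L, ws@params$linear$b, "+")
        rSum <- out + zlin - y; rLin <- zlin - y
        rSum[!vm, ] <- 0; rLin[!vm, ] <- 0
        maeSum <- sum(abs(rSum)) / nValid
        maeLin <- sum(abs(rLin)) / nValid
        list(total = maeSum + lambda * maeLin, maeSum = maeSum, maeLinear = maeLin)
    } else {
        r <- out - y
        r[!vm, ] <- 0
        list(total = sum(abs(r)) / nValid)
    }
}

#' Apply a trained network to a zero-filled k-space frame
#'
#' Normalizes the input by the training scale, runs the convolution stack
#' (same-size zero-padded convolutions; for rRAKI the sum of both paths),
#' denormalizes, and enforces consistency with the measured rows.
#'
#' @param ws a \linkS4class{WeightSet}.
#' @param zeroFilled complex array \code{[nCoils, ny, nx]} with missing rows zero.
#' @param mask the \linkS4class{SamplingMask}.
#' @param dc apply the data-consistency step (default \code{TRUE}).
#' @return complex array \code{[nCoils, ny, nx]}.
#' @export
applyNetwork <- function(ws, zeroFilled, mask, dc = TRUE) {
    d <- frameDims(zeroFilled)
    spec <- ws@spec
    if (d[1] != spec@nCoils) stop("coil count mismatch", call. = FALSE)
    ny <- d[2]; nx <- d[3]
    x <- chanMatrix(splitComplex(zeroFilled / ws@normScale))
    idxCache <- idxCacheFor(spec, ny, nx)
    serial <- spec@layers
    nSer <- length(serial)
    params <- ws@params[seq_len(nSer)]
    fw <- convForward(serial, x, ny, nx, params, idxCache)
    out <- fw$out
    if (length(spec@linearPath)) {
        l <- spec@linearPath
        xc <- im2col(x, ny, nx, l$ky, l$kx, idxCache[[paste(l$ky, l$kx)]])
        out <- out + sweep(xc %*% ws@params$linear$W, 2L, ws@params$linear$b, "+")
    }
    pred <- mergeComplex(unchanMatrix(out, 2L * spec@nCoils, ny, nx)) * ws@normScale
    if (dc) dataConsistency(pred, zeroFilled, mask) else pred
}
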