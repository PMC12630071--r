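# Training/reuse orchestration across the (slice, phase) grid: per-frame
# scan-specific training, multi-phase sharing (mp: one trained phase per
# slice reused across the cycle), multi-slice sharing (ms(1/B): the middle
# slice of each group of B consecutive slices trained per phase), and the
# combined mp-ms strategy (one trained phase of the middle slice per group).
# Slice and phase indices in plans are 1-based.

#' Describe a weight-sharing strategy
#'
#' @param name one of \code{"per_frame"}, \code{"mp"}, \code{"ms"}, \code{"mp_ms"}.
#' @param groupSize slice-group size for the ms variants (1, 3, 5 or 9).
#' @param allSlicesOneModel for \code{"ms"}: train one joint model per phase
#'   on all slices' ACS (the (9/9) ablation arm).
#' @param phaseSelection \code{"random"} (seeded draw per slice/group) or
#'   \code{"fixed"} (use \code{fixedPhase}).
#' @param fixedPhase 1-based phase used when \code{phaseSelection = "fixed"};
#'   \code{NULL} means the middle phase.
#' @param seed seed for the random phase draws.
#' @return list of class \code{"StrategySpec"}.
#' @export
strategySpec <- function(name = c("per_frame", "mp", "ms", "mp_ms"),
                         groupSize = 3L, allSlicesOneModel = FALSE,
                         phaseSelection = c("random", "fixed"),
                         fixedPhase = NULL, seed = 1L) {
    name <- match.arg(name)
    phaseSelection <- match.arg(phaseSelection)
    groupSize <- asInt(groupSize, "groupSize")
    if (!allSlicesOneModel && !groupSize %in% c(1L, 3L, 5L, 9L))
        stop("groupSize must be one of 1, 3, 5, 9", call. = FALSE)
    structure(list(name = name, groupSize = groupSize,
                   allSlicesOneModel = isTRUE(allSlicesOneModel),
                   phaseSelection = phaseSelection, fixedPhase = fixedPhase,
                   seed = asInt(seed, "seed")),
              class = "StrategySpec")
}

pickPhase <- function(spec, nPhases, key) {
    if (spec$phaseSelection == "fixed") {
        p <- if (is.null(spec$fixedPhase)) (nPhases + 1L) %/% 2L else spec$fixedPhase
        return(as.integer(p))
    }
    withSeed(subSeed(spec$seed, "phase-pick", key), sample.int(nPhases, 1L))
}

sliceGroups <- function(nSlices, groupSize) {
    starts <- seq.int(1L, nSlices, by = groupSize)
    lapply(starts, function(s) seq.int(s, min(s + groupSize - 1L, nSlices)))
}

planEntry <- function(trainSlices, trainPhase, coverSlices, coverPhases) {
    list(train = list(slices = as.integer(trainSlices), phase = as.integer(trainPhase)),
         covers = expand.grid(slice = as.integer(coverSlices),
                              phase = as.integer(coverPhases)))
}

#' Build a training plan for a cine stack
#'
#' Each plan entry names the (slice(s), phase) whose ACS trains one model and
#' the set of frames reconstructed with it; every frame of the stack is
#' covered exactly once.
#'
#' \itemize{
#'   \item \code{per_frame}: one training per (slice, phase);
#'   \item \code{mp}: one training per slice at one (seeded-random or fixed)
#'     phase, reused across all phases of that slice;
#'   \item \code{ms}: per group of \code{groupSize} consecutive slices, train
#'     the group's middle slice at every phase (with
#'     \code{allSlicesOneModel}, train one joint model per phase on all
#'     slices);
#'   \item \code{mp_ms}: per group, train the middle slice at one phase and
#'     reuse across the whole group and cycle.
#' }
#'
#' @param nSlices,nPhases stack geometry.
#' @param spec a \code{StrategySpec}.
#' @return list of plan entries (class \code{"TrainingPlan"}).
#' @examples
#' length(makePlan(9, 23, strategySpec("per_frame")))          # 207
#' length(makePlan(9, 23, strategySpec("mp")))                 # 9
#' length(makePlan(9, 23, strategySpec("mp_ms", groupSize = 3))) # 3
#' @export
makePlan <- function(nSlices, nPhases, spec) {
    stopifnot2(inherits(spec, "StrategySpec"), "expected a StrategySpec")
    nSlices <- asInt(nSlices, "nSlices"); nPhases <- asInt(nPhases, "nPhases")
    if (nSlices < 1L) stop("nSlices must be >= 1", call. = FALSE)
    if (spec$name %in% c("ms", "mp_ms") && !spec$allSlicesOneModel &&
        spec$groupSize > nSlices)
        stop("groupSize exceeds nSlices", call. = FALSE)
    entries <- switch(spec$name,
        per_frame = {
            out <- list()
            for (s in seq_len(nSlices)) for (p in seq_len(nPhases))
                out[[length(out) + 1L]] <- planEntry(s, p, s, p)
            out
        },
        mp = lapply(seq_len(nSlices), function(s)
            planEntry(s, pickPhase(spec, nPhases, s), s, seq_len(nPhases))),
        ms = {
            if (spec$allSlicesOneModel) {
                lapply(seq_len(nPhases), function(p)
                    planEntry(seq_len(nSlices), p, seq_len(nSlices), p))
            } else {
                out <- list()
                for (g in sliceGroups(nSlices, spec$groupSize)) {
                    mid <- g[(length(g) + 1L) %/% 2L]
                    for (p in seq_len(nPhases))
                        out[[length(out) + 1L]] <- planEntry(mid, p, g, p)
                }
                out
            }
        },
        mp_ms = lapply(sliceGroups(nSlices, spec$groupSize), function(g) {
            mid <- g[(length(g) + 1L) %/% 2L]
            planEntry(mid, pickPhase(spec, nPhases, mid), g, seq_len(nPhases))
        }))
    structure(entries, class = "TrainingPlan")
}

#' Verify that a plan covers every frame exactly once
#' @param plan a \code{TrainingPlan}.
#' @param nSlices,nPhases stack geometry.
#' @return \code{TRUE} (invisibly) or an error.
#' @export
checkPlanCoverage <- function(plan, nSlices, nPhases) {
    cov <- do.call(rbind, lapply(plan, `[[`, "covers"))
    key <- paste(cov$slice, cov$phase)
    all_ <- paste(rep(seq_len(nSlices), each = nPhases), rep(seq_len(nPhases), nSlices))
    if (anyDuplicated(key) || !setequal(key, all_))
        stop("plan does not cover every frame exactly once", call. = FALSE)
    invisible(TRUE)
}

#' Canonical multi-slice ablation plans for a 9-slice stack
#'
#' Returns the (1/1), (9/9), (1/9), (1/5) and (1/3) multi-slice plans:
#' per-slice self-training; one joint model per phase; train the middle
#' slice only; train slices 3 and 7 (1-based) covering slices 1-5 / 6-9;
#' train the middle slice of each group of three.
#'
#' @param nSlices must be 9 (the canonical ablation geometry).
#' @param nPhases cardiac phases.
#' @return named list of \code{TrainingPlan}s.
#' @export
msVariants <- function(nSlices = 9L, nPhases) {
    if (nSlices != 9L) stop("the canonical ablation uses 9 slices", call. = FALSE)
    v11 <- makePlan(nSlices, nPhases, strategySpec("per_frame"))
    v99 <- makePlan(nSlices, nPhases, strategySpec("ms", allSlicesOneModel = TRUE))
    v19 <- makePlan(nSlices, nPhases, strategySpec("ms", groupSize = 9L))
    v15 <- makePlan(nSlices, nPhases, strategySpec("ms", groupSize = 5L))
    v13 <- makePlan(nSlices, nPhases, strategySpec("ms", groupSize = 3L))
    list("1/1" = v11, "9/9" = v99, "1/9" = v19, "1/5" = v15, "1/3" = v13)
}

#' Run a reconstruction strategy over a cine stack
#'
#' Retrospectively undersamples every frame with the mask, trains exactly the
#' plan's models on their ACS blocks, applies each model to all frames it
#' covers (network/kernel application, data consistency, inverse FFT,
#' sum-of-squares), and records a four-part wall-clock timing breakdown per
#' frame (data loading, training, evaluation, reconstruction; training time
#' is attributed to the trained frame of each entry).
#'
#' @param cine a \linkS4class{CineKSpace} or \linkS4class{CineTruth} (its
#'   fully sampled k-space is undersampled internally).
#' @param mask a \linkS4class{SamplingMask}.
#' @param method \code{"grappa"}, \code{"sraki"}, \code{"raki"} or \code{"rraki"}
#'   (for GRAPPA, "training" is kernel calibration on the same plans).
#' @param spec a \code{StrategySpec}.
#' @param hyper a \code{TrainingHyper} (ignored for GRAPPA).
#' @param grappaSpec kernel geometry for GRAPPA (default 5 x 5 at the mask R).
#' @return a \linkS4class{ReconResult}.
#' @export
runStrategy <- function(cine, mask, method = c("sraki", "raki", "rraki", "grappa"),
                        spec = strategySpec("per_frame"), hyper = trainingHyper(),
                        grappaSpec = grappaKernelSpec(R = mask@R)) {
    method <- match.arg(method)
    kd <- if (is(cine, "CineTruth")) cine@kspace@kdata else cine@kdata
    d <- dim(kd)
    nS <- d[1]; nP <- d[2]; ny <- d[4]; nx <- d[5]
    plan <- makePlan(nS, nP, spec)
    checkPlanCoverage(plan, nS, nP)
    netMethod <- toupper(method)
    netSpec <- if (method != "grappa") buildNetwork(netMethod, d[3])
    rf <- if (method != "grappa") receptiveField(netSpec)

    images <- array(0, c(nS, nP, ny, nx))
    timing <- data.frame(slice = rep(seq_len(nS), each = nP),
                         phase = rep(seq_len(nP), nS),
                         load_s = 0, train_s = 0, eval_s = 0, recon_s = 0)
    trow <- function(s, p) which(timing$slice == s & timing$phase == p)
    weights <- vector("list", length(plan))

    zf <- array(0i, d)   # undersampled stack, filled lazily per frame
    zfDone <- matrix(FALSE, nS, nP)
    getZF <- function(s, p) {
        if (!zfDone[s, p]) {
            zf[s, p, , , ] <<- undersample(array(kd[s, p, , , ], d[3:5]), mask)
            zfDone[s, p] <<- TRUE
        }
        array(zf[s, p, , , ], d[3:5])
    }

    for (ei in seq_along(plan)) {
        e <- plan[[ei]]
        tSlices <- e$train$slices; tPhase <- e$train$phase
        homeRow <- trow(tSlices[1], tPhase)

        t0 <- proc.time()[["elapsed"]]
        pairs <- lapply(tSlices, function(s) {
            frame <- getZF(s, tPhase)
            acs <- extractACS(frame, mask)
            if (method == "grappa") acs else makeTrainingPair(acs, mask, rf = rf)
        })
        tLoad <- proc.time()[["elapsed"]] - t0
        timing$load_s[homeRow] <- timing$load_s[homeRow] + tLoad

        t0 <- proc.time()[["elapsed"]]
        ws <- if (method == "grappa") {
            grappaCalibrate(pairs[[1]], grappaSpec,
                            provenance = list(slice = tSlices, phase = tPhase))
        } else {
            hp <- hyper
            hp$seed <- subSeed(hyper$seed, "train", tSlices[1], tPhase)
            trainNetwork(netSpec, if (length(pairs) == 1L) pairs[[1]] else pairs,
                         hp, provenance = list(slice = tSlices, phase = tPhase))
        }
        tTrain <- proc.time()[["elapsed"]] - t0
        timing$train_s[homeRow] <- timing$train_s[homeRow] + tTrain
        weights[[ei]] <- ws

        for (ri in seq_len(nrow(e$covers))) {
            s <- e$covers$slice[ri]; p <- e$covers$phase[ri]
            row <- trow(s, p)
            t0 <- proc.time()[["elapsed"]]
            frame <- getZF(s, p)
            filled <- if (method == "grappa") {
                dataConsistency(grappaApply(ws, frame, mask), frame, mask)
            } else applyNetwork(ws, frame, mask)
            t1 <- proc.time()[["elapsed"]]
            images[s, p, , ] <- sosCombine(ifft2c(filled))
            t2 <- proc.time()[["elapsed"]]
            timing$eval_s[row] <- timing$eval_s[row] + (t1 - t0)
            timing$recon_s[row] <- timing$recon_s[row] + (t2 - t1)
        }
    }
    new("ReconResult", images = images, timing = timing, plan = unclass(plan),
        weights = weights, method = method)
}
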