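# Internal helpers: seeded substreams, index shifts, argument checks.

#' Derive a reproducible integer sub-seed from a master seed and a stream name
#'
#' All phantom and training randomness flows from one master seed through
#' named streams so that every component is independently reproducible.
#' @param seed master integer seed.
#' @param ... name components (coerced to character) identifying the stream.
#' @return an integer in [0, 2^31 - 2].
#' @keywords internal
subSeed <- function(seed, ...) {
    name <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
    h <- as.double(seed %% 2147483647L)
    for (ch in utf8ToInt(name))
        h <- (h * 31 + ch) %% 2147483647
    as.integer(h)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# fftshift/ifftshift index permutations: DC at 0-based floor(n/2) <-> index 1.
fftshiftIdx <- function(n) {
    s <- n %/% 2L
    c(seq.int(n - s + 1L, n), seq_len(n - s))
}
ifftshiftIdx <- function(n) {
    s <- n %/% 2L
    c(seq.int(s + 1L, n), seq_len(s))
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

asInt <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x != round(x))
        stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
    as.integer(x)
}
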