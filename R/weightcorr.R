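# Stability analysis of trained kernel weights across cardiac phases and
# slices: the absolute-covariance Pearson coefficient
# rho(X, Y) = |Cov(X, Y)| / (sigma_X * sigma_Y), computed between each
# weight set and a reference (conventionally the middle slice/phase).

#' Flatten a weight set to a comparable real vector
#'
#' Network weight sets flatten layer by layer (weights then bias, linear
#' path last); GRAPPA kernels flatten the per-offset complex matrices as
#' interleaved real/imaginary parts. Biases are included. The flattening
#' order is fixed, so vectors from like-trained models are comparable
#' entry by entry.
#'
#' @param ws a \linkS4class{WeightSet} or \linkS4class{GrappaWeights}.
#' @return numeric vector.
#' @export
flattenWeights <- function(ws) {
    if (is(ws, "GrappaWeights")) {
        v <- unlist(lapply(ws@weights, function(W) {
            rbind(Re(as.vector(W)), Im(as.vector(W)))
        }))
        return(as.numeric(v))
    }
    stopifnot2(is(ws, "WeightSet"), "expected a WeightSet or GrappaWeights")
    as.numeric(unlist(lapply(ws@params, function(p) c(as.numeric(p$W), p$b))))
}

#' Absolute-covariance Pearson coefficient of two weight vectors
#'
#' \code{|Cov(X, Y)| / (sd(X) * sd(Y))} with population (divide-by-N)
#' moments; the ratio is invariant to that convention. Values lie in [0, 1];
#' 1 for the reference compared with itself (and for any sign flip).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation magnitude in [0, 1].
#' @export
pearsonAbs <- function(x, y) {
    if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
    if (length(x) < 2L) stop("need at least 2 entries", call. = FALSE)
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    cv <- sum((x - mx) * (y - my)) / n
    vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
    if (vx == 0 || vy == 0)
        stop("undefined correlation: zero-variance input", call. = FALSE)
    # denominator as sqrt of the variance product: the self-correlation is
    # then exactly 1 in floating point
    min(abs(cv) / sqrt(vx * vy), 1)
}

#' Correlate a collection of weight sets against a reference
#'
#' @param weights list of \linkS4class{WeightSet} / \linkS4class{GrappaWeights},
#'   each carrying (slice, phase) provenance.
#' @param refSlice,refPhase provenance of the reference set (must be present).
#' @return data.frame (class \code{"CorrelationTable"}) with columns
#'   \code{slice}, \code{phase}, \code{rho}; attribute \code{reference}.
#' @export
correlationTable <- function(weights, refSlice, refPhase) {
    stopifnot2(length(weights) >= 1L, "empty weight list")
    prov <- lapply(weights, function(w) w@provenance)
    sl <- vapply(prov, function(p) p$slice[1], numeric(1))
    ph <- vapply(prov, function(p) p$phase[1], numeric(1))
    refIdx <- which(sl == refSlice & ph == refPhase)
    if (!length(refIdx))
        stop("reference (slice, phase) not present in the weight list", call. = FALSE)
    vecs <- lapply(weights, flattenWeights)
    lens <- lengths(vecs)
    if (length(unique(lens)) != 1L)
        stop("weight vectors have differing lengths", call. = FALSE)
    ref <- vecs[[refIdx[1]]]
    rho <- vapply(vecs, function(v) pearsonAbs(ref, v), numeric(1))
    out <- data.frame(slice = sl, phase = ph, rho = rho)
    attr(out, "reference") <- c(slice = refSlice, phase = refPhase)
    class(out) <- c("CorrelationTable", "data.frame")
    out
}

#' Write a correlation table as tab-separated values
#' @param tab a \code{CorrelationTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCorrelationTable <- function(tab, path) {
    utils::write.table(as.data.frame(tab), path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}
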