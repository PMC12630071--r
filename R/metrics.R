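# Reference-based image quality metrics on the heart region of interest:
# PSNR (dB, peak from the reference ROI), NMSE (MSE normalized by the
# reference ROI energy), and the three-component SSIM with a 7x7 uniform
# window, computed after normalizing both images by the reference ROI peak
# (data range L = 1, c1 = (0.01 L)^2, c2 = (0.03 L)^2, c3 = c2 / 2).

roiCrop <- function(img, roi) {
    if (is.null(roi)) return(img)
    img[(roi$row0 + 1L):roi$row1, (roi$col0 + 1L):roi$col1, drop = FALSE]
}

checkPair <- function(reference, estimate) {
    if (!all(dim(reference) == dim(estimate)))
        stop("reference and estimate must have identical shapes", call. = FALSE)
}

#' Peak signal-to-noise ratio on an ROI
#'
#' \code{10 * log10(MAX_I^2 / MSE)} with \code{MAX_I} the maximum reference
#' pixel in the ROI and the MSE averaged over ROI pixels; returns \code{Inf}
#' when the images agree exactly.
#'
#' @param reference,estimate real image matrices of identical shape.
#' @param roi ROI record from [heartROI()] (\code{NULL}: whole image).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, estimate, roi = NULL) {
    checkPair(reference, estimate)
    I <- roiCrop(reference, roi); Y <- roiCrop(estimate, roi)
    if (all(I == 0)) stop("reference is identically zero on the ROI", call. = FALSE)
    mse <- mean((I - Y)^2)
    if (mse == 0) return(Inf)
    10 * log10(max(I)^2 / mse)
}

#' Normalized mean squared error on an ROI
#'
#' \code{MSE / mean(I^2)} over ROI pixels.
#'
#' @inheritParams psnr
#' @return dimensionless NMSE >= 0.
#' @export
nmse <- function(reference, estimate, roi = NULL) {
    checkPair(reference, estimate)
    I <- roiCrop(reference, roi); Y <- roiCrop(estimate, roi)
    den <- mean(I^2)
    if (den == 0) stop("reference is identically zero on the ROI", call. = FALSE)
    mean((I - Y)^2) / den
}

# Sliding-window box means over all fully contained windows (valid mode).
boxMeans <- function(m, w) {
    cs <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    cs[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
    nr <- nrow(m) - w + 1L; nc <- ncol(m) - w + 1L
    (cs[(w + 1L):(nrow(m) + 1L), (w + 1L):(ncol(m) + 1L), drop = FALSE] -
     cs[1:nr, (w + 1L):(ncol(m) + 1L), drop = FALSE] -
     cs[(w + 1L):(nrow(m) + 1L), 1:nc, drop = FALSE] +
     cs[1:nr, 1:nc, drop = FALSE]) / (w * w)
}

#' Structural similarity on an ROI
#'
#' Mean over all fully contained \code{window x window} ROI positions of the
#' three-component SSIM (luminance x contrast x structure) with uniform
#' windows. Both images are first normalized by the larger of the two ROI
#' maxima (a symmetric data range of 1, so \code{ssim(x, y) == ssim(y, x)}
#' exactly).
#'
#' @inheritParams psnr
#' @param window odd window side (default 7).
#' @param c1,c2,c3 stabilization constants (defaults \code{(0.01)^2},
#'   \code{(0.03)^2}, \code{c2/2} on the unit data range).
#' @return SSIM in [-1, 1]; 1 for identical images.
#' @export
ssim <- function(reference, estimate, roi = NULL, window = 7L,
                 c1 = 0.01^2, c2 = 0.03^2, c3 = c2 / 2) {
    checkPair(reference, estimate)
    I <- roiCrop(reference, roi); Y <- roiCrop(estimate, roi)
    if (window > min(dim(I)))
        stop("window larger than the ROI", call. = FALSE)
    mx <- max(max(I), max(Y))
    if (mx == 0) stop("reference is identically zero on the ROI", call. = FALSE)
    x <- I / mx; y <- Y / mx
    mux <- boxMeans(x, window); muy <- boxMeans(y, window)
    sxx <- boxMeans(x * x, window) - mux^2
    syy <- boxMeans(y * y, window) - muy^2
    sxy <- boxMeans(x * y, window) - mux * muy
    sxx[sxx < 0] <- 0; syy[syy < 0] <- 0
    sx <- sqrt(sxx); sy <- sqrt(syy)
    lum <- (2 * mux * muy + c1) / (mux^2 + muy^2 + c1)
    con <- (2 * sx * sy + c2) / (sxx + syy + c2)
    str <- (sxy + c3) / (sx * sy + c3)
    mean(lum * con * str)
}

#' Evaluate a reconstructed stack against the ground truth
#'
#' Per-frame PSNR/SSIM/NMSE on the heart ROI, plus mean and standard
#' deviation aggregates across all frames.
#'
#' @param recon a \linkS4class{ReconResult} (or a real array
#'   \code{[slice, phase, ny, nx]}).
#' @param truth a \linkS4class{CineTruth}.
#' @return list of class \code{"MetricsReport"} with \code{perFrame}
#'   (data.frame: slice, phase, psnr, ssim, nmse) and \code{summary}
#'   (data.frame: metric, mean, sd).
#' @export
evaluateStack <- function(recon, truth) {
    imgs <- if (is(recon, "ReconResult")) recon@images else recon
    stopifnot2(is(truth, "CineTruth"), "expected a CineTruth")
    stopifnot2(all(dim(imgs) == dim(truth@sosImages)), "shape mismatch")
    roi <- truth@heartROI
    d <- dim(imgs)
    rows <- expand.grid(phase = seq_len(d[2]), slice = seq_len(d[1]))[, 2:1]
    per <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
        s <- rows$slice[i]; p <- rows$phase[i]
        I <- matrix(truth@sosImages[s, p, , ], d[3], d[4])
        Y <- matrix(imgs[s, p, , ], d[3], d[4])
        data.frame(slice = s, phase = p,
                   psnr = psnr(I, Y, roi), ssim = ssim(I, Y, roi),
                   nmse = nmse(I, Y, roi))
    }))
    summ <- data.frame(metric = c("psnr", "ssim", "nmse"),
                       mean = c(mean(per$psnr), mean(per$ssim), mean(per$nmse)),
                       sd = c(stats::sd(per$psnr), stats::sd(per$ssim),
                              stats::sd(per$nmse)))
    structure(list(perFrame = per, summary = summ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
    cat(sprintf("MetricsReport: %d frame(s)\n", nrow(x$perFrame)))
    for (i in seq_len(nrow(x$summary)))
        cat(sprintf("  %s: %.4g +/- %.4g\n", x$summary$metric[i],
                    x$summary$mean[i], x$summary$sd[i]))
    invisible(x)
}

#' Write a metrics report as a delimited table
#'
#' Tab-separated per-frame table followed by a commented summary block in
#' \code{mean +/- sd} form.
#'
#' @param report a \code{MetricsReport}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(report$perFrame, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    for (i in seq_len(nrow(report$summary)))
        writeLines(sprintf("# %s\t%.6g +/- %.6g", report$summary$metric[i],
                           report$summary$mean[i], report$summary$sd[i]), con)
    invisible(path)
}
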