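#' Full-reference similarity metrics between view images
#'
#' `viewRMSE()`, `viewPSNR()`, `viewSSIM()` and `viewFSIM()` compare one
#' original/defaced pair of rendered view images (numeric matrices in
#' [0,1]); `similarityFeatures()` computes all four for each of the five
#' corresponding views of two \code{\linkS4class{ViewSet}}s and aggregates
#' (arithmetic mean by default) across views.
#'
#' PSNR is `20 log10(L / RMSE)` capped at `psnrCap` so identical images
#' yield a finite feature. SSIM uses Gaussian-windowed local statistics
#' (sigma 1.5, width 11, population covariance) evaluated on the valid
#' interior and averaged, with C1 = (K1 L)^2 and C2 = (K2 L)^2. FSIM is
#' documented in [viewFSIM()].
#'
#' @param a,b numeric matrices of identical shape with values in [0,1].
#' @param config a [similarityConfig()].
#' @return a scalar metric value; `similarityFeatures()` returns a one-row
#'   data.frame with columns rmse, psnr, ssim, fsim.
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' viewRMSE(img, img)                      # 0
#' viewSSIM(img, pmin(img + 0.1, 1))       # < 1
#' @export
viewRMSE <- function(a, b) {
  checkPair(a, b)
  sqrt(mean((a - b)^2))
}

#' @rdname viewRMSE
#' @export
viewPSNR <- function(a, b, config = similarityConfig()) {
  r <- viewRMSE(a, b)
  if (r == 0) return(config$psnrCap)
  min(20 * log10(config$dynamicRange / r), config$psnrCap)
}

#' @rdname viewRMSE
#' @export
viewSSIM <- function(a, b, config = similarityConfig()) {
  checkPair(a, b)
  w <- config$ssimWindow
  if (min(dim(a)) < w)
    stop("image smaller than the SSIM window (", w, " px)")
  k <- gaussKernel1d(config$ssimSigma, w)
  L <- config$dynamicRange
  C1 <- (config$ssimK1 * L)^2
  C2 <- (config$ssimK2 * L)^2
  ux <- gaussFiltValid(a, k)
  uy <- gaussFiltValid(b, k)
  uxx <- gaussFiltValid(a * a, k)
  uyy <- gaussFiltValid(b * b, k)
  uxy <- gaussFiltValid(a * b, k)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  vxy <- uxy - ux * uy
  s <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' @rdname viewRMSE
#' @param viewsOrig,viewsDefaced \code{\linkS4class{ViewSet}}s of the
#'   original and defaced scans.
#' @export
similarityFeatures <- function(viewsOrig, viewsDefaced,
                               config = similarityConfig()) {
  stopifnot(is(viewsOrig, "ViewSet"), is(viewsDefaced, "ViewSet"))
  if (!identical(names(viewsOrig@images), names(viewsDefaced@images)) ||
      viewsOrig@resolution != viewsDefaced@resolution)
    stop("view sets do not match (names or resolution differ)")
  per <- vapply(names(viewsOrig@images), function(nm) {
    a <- viewsOrig@images[[nm]]
    b <- viewsDefaced@images[[nm]]
    c(rmse = viewRMSE(a, b),
      psnr = viewPSNR(a, b, config),
      ssim = viewSSIM(a, b, config),
      fsim = viewFSIM(a, b, config))
  }, numeric(4))
  agg <- switch(config$aggregation,
                mean = rowMeans(per),
                min = apply(per, 1, min))
  # for rmse, "worst view" aggregation means the maximum error
  if (config$aggregation == "min") agg["rmse"] <- max(per["rmse", ])
  data.frame(rmse = agg[["rmse"]], psnr = agg[["psnr"]],
             ssim = agg[["ssim"]], fsim = agg[["fsim"]])
}

checkPair <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!identical(dim(a), dim(b)))
    stop("image shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

gaussKernel1d <- function(sigma, width) {
  r <- (width - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable 'valid' convolution with a symmetric 1D kernel
convValidCols <- function(X, k) {
  n <- nrow(X)
  w <- length(k)
  out <- k[1] * X[seq_len(n - w + 1), , drop = FALSE]
  for (i in 2:w)
    out <- out + k[i] * X[i:(n - w + i), , drop = FALSE]
  out
}

gaussFiltValid <- function(X, k) {
  t(convValidCols(t(convValidCols(X, k)), k))
}
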