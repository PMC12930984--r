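# Feature Similarity Index (FSIM) for grayscale images.
#
# FSIM scores local structure agreement where it matters perceptually:
# per-pixel similarity of phase congruency (PC) and of gradient magnitude
# (Scharr operator) are multiplied and pooled with weights max(PC1, PC2),
# so pixels with salient low-level features dominate the score. PC is
# computed from a log-Gabor filter bank (4 scales, 4 orientations, minimum
# wavelength 6, scale multiplier 2, sigmaOnf 0.55) with the conventional
# noise-energy compensation. Contrast constants T1 (PC term) and T2
# (gradient term) follow the conventional 8-bit parameterization; inputs in
# [0, L] are rescaled to [0, 255] internally. The chrominance extension is
# omitted: renders are grayscale.

#' @rdname viewRMSE
#' @export
viewFSIM <- function(a, b, config = similarityConfig()) {
  checkPair(a, b)
  if (min(dim(a)) < 32)
    stop("FSIM requires images of at least 32 px per side")
  s <- 255 / config$dynamicRange
  a <- a * s
  b <- b * s
  # conventional resolution normalization: average and subsample so the
  # smaller side is ~256 px (no-op for <= 384 px inputs)
  f <- max(1, round(min(dim(a)) / 256))
  if (f > 1) {
    a <- blockSubsample(a, f)
    b <- blockSubsample(b, f)
  }
  pc1 <- phaseCongruency(a, nscale = config$fsimScales,
                         norient = config$fsimOrients)
  pc2 <- phaseCongruency(b, nscale = config$fsimScales,
                         norient = config$fsimOrients)
  g1 <- scharrGradMag(a)
  g2 <- scharrGradMag(b)
  T1 <- config$fsimT1
  T2 <- config$fsimT2
  sPC <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  sG <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  den <- sum(pcm)
  if (den < 1e-12) {
    # constant images carry no phase congruency anywhere
    if (isTRUE(all.equal(a, b, tolerance = 0))) return(1.0)
    return(mean(sPC * sG))
  }
  sum(sPC * sG * pcm) / den
}

blockSubsample <- function(x, f) {
  k <- matrix(1 / (f * f), f, f)
  ave <- conv2same(x, k)
  ave[seq(1, nrow(x), by = f), seq(1, ncol(x), by = f), drop = FALSE]
}

# zero-padded 'same' cross-correlation with a small kernel
conv2same <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  n <- nrow(x); m <- ncol(x)
  xp <- matrix(0, n + kr - 1, m + kc - 1)
  xp[pr + seq_len(n), pc + seq_len(m)] <- x
  out <- matrix(0, n, m)
  for (i in seq_len(kr))
    for (j in seq_len(kc))
      if (k[i, j] != 0)
        out <- out + k[i, j] * xp[i + seq_len(n) - 1, j + seq_len(m) - 1]
  out
}

scharrGradMag <- function(x) {
  dx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  gx <- conv2same(x, dx)
  gy <- conv2same(x, t(dx))
  sqrt(gx^2 + gy^2)
}

ifftshift2 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  fr <- floor(n / 2); fc <- floor(p / 2)
  m[c((fr + 1):n, seq_len(fr)), c((fc + 1):p, seq_len(fc)), drop = FALSE]
}

# 2D phase congruency (log-Gabor filter bank with noise compensation)
phaseCongruency <- function(im, nscale = 4L, norient = 4L,
                            minWaveLength = 6, mult = 2, sigmaOnf = 0.55,
                            dThetaOnSigma = 1.2, k = 2, epsilon = 1e-4) {
  rows <- nrow(im); cols <- ncol(im)
  xr <- if (cols %% 2 == 1) (-(cols - 1) / 2):((cols - 1) / 2) / (cols - 1)
        else (-cols / 2):(cols / 2 - 1) / cols
  yr <- if (rows %% 2 == 1) (-(rows - 1) / 2):((rows - 1) / 2) / (rows - 1)
        else (-rows / 2):(rows / 2 - 1) / rows
  x <- matrix(xr, rows, cols, byrow = TRUE)
  y <- matrix(yr, rows, cols)
  radius <- ifftshift2(sqrt(x^2 + y^2))
  theta <- ifftshift2(atan2(-y, x))
  radius[1, 1] <- 1
  sintheta <- sin(theta)
  costheta <- cos(theta)
  lp <- 1 / (1 + (radius / 0.45)^30)   # Butterworth low-pass, cutoff .45, order 15
  logGabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    wavelength <- minWaveLength * mult^(s - 1)
    fo <- 1 / wavelength
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigmaOnf)^2)) * lp
    lg[1, 1] <- 0
    logGabor[[s]] <- lg
  }
  IM <- fft(im)
  thetaSigma <- pi / norient / dThetaOnSigma
  energyAll <- matrix(0, rows, cols)
  anAll <- matrix(0, rows, cols)
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * thetaSigma^2))
    sumE <- matrix(0, rows, cols)
    sumO <- matrix(0, rows, cols)
    sumAn <- matrix(0, rows, cols)
    eo <- vector("list", nscale)
    tau <- 0
    for (s in seq_len(nscale)) {
      filt <- logGabor[[s]] * spread
      eo[[s]] <- fft(IM * filt, inverse = TRUE) / (rows * cols)
      an <- Mod(eo[[s]])
      sumAn <- sumAn + an
      sumE <- sumE + Re(eo[[s]])
      sumO <- sumO + Im(eo[[s]])
      if (s == 1) tau <- median(an) / sqrt(log(4))
    }
    xEnergy <- sqrt(sumE^2 + sumO^2) + epsilon
    meanE <- sumE / xEnergy
    meanO <- sumO / xEnergy
    energy <- matrix(0, rows, cols)
    for (s in seq_len(nscale)) {
      e <- Re(eo[[s]]); o2 <- Im(eo[[s]])
      energy <- energy + e * meanE + o2 * meanO - abs(e * meanO - o2 * meanE)
    }
    totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noiseMean <- totalTau * sqrt(pi / 2)
    noiseSigma <- totalTau * sqrt((4 - pi) / 2)
    threshold <- (noiseMean + k * noiseSigma) / 1.7
    energy <- pmax(energy - threshold, 0)
    energyAll <- energyAll + energy
    anAll <- anAll + sumAn
  }
  energyAll / (anAll + epsilon)
}
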