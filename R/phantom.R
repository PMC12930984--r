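#' Synthetic head phantoms with facial features
#'
#' `phantomSpec()` parameterizes a head-shaped volume: an ellipsoidal head
#' with an interior brain compartment and four facial-feature protrusions
#' (nose, left/right eyes, mouth) on the anterior surface, piecewise-
#' constant tissue intensities plus additive Gaussian noise. Per-subject
#' shape jitter (driven by `subjectSeed`) is shared across all of a
#' subject's scans, creating the within-subject correlation that makes the
#' group-fold constraint meaningful; per-scan noise is driven by `seed`.
#'
#' @param gridSize voxels per axis (cubic grid). Default 96.
#' @param noiseSd additive Gaussian noise sd inside the head, in intensity
#'   units. Default 0.02.
#' @param jitterSd relative sd of per-subject shape jitter. Default 0.02.
#' @param subjectId subject identifier.
#' @param scanId scan identifier.
#' @param subjectSeed seed for the subject-level shape jitter.
#' @param seed seed for the scan-level noise.
#' @return a named parameter list.
#' @export
phantomSpec <- function(gridSize = 96L, noiseSd = 0.02, jitterSd = 0.02,
                        subjectId = "subj1", scanId = paste0(subjectId, "_s1"),
                        subjectSeed = 1L, seed = 1L) {
  stopifnot(gridSize >= 32, noiseSd >= 0, jitterSd >= 0)
  list(gridSize = as.integer(gridSize), noiseSd = noiseSd,
       jitterSd = jitterSd, subjectId = subjectId, scanId = scanId,
       subjectSeed = as.integer(subjectSeed), seed = as.integer(seed))
}

featureNames4 <- function() c("nose", "left_eye", "right_eye", "mouth")

#' @rdname phantomSpec
#' @param spec a [phantomSpec()].
#' @return `generatePhantom()` returns a \code{\linkS4class{HeadPhantom}}:
#'   the scan, head and brain masks, and per-feature voxel indices ordered
#'   surface-inward (outermost first) for controlled removal.
#' @examples
#' ph <- generatePhantom(phantomSpec(gridSize = 48))
#' brainToHeadRatio(ph@brainMask, ph@headMask)
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  n <- spec$gridSize
  # subject-level shape jitter, shared across the subject's scans
  set.seed(childSeed(spec$subjectSeed, 101L))
  jit <- function() 1 + spec$jitterSd * rnorm(1)
  cx <- (n + 1) / 2
  cy <- (n + 1) / 2 - 0.02 * n
  cz <- (n + 1) / 2 + 0.02 * n
  headAx <- c(0.30, 0.36, 0.38) * n * c(jit(), jit(), jit())
  brainAx <- c(0.22, 0.25, 0.27) * n * c(jit(), jit(), jit())
  brainCenter <- c(cx, cy - 0.04 * n, cz + 0.04 * n)
  eyeOff <- 0.13 * n * jit()
  eyeZ <- cz + 0.06 * n
  eyeR <- 0.045 * n * jit()
  noseAx <- c(0.06, 0.10, 0.07) * n * jit()
  noseZ <- cz - 0.02 * n
  mouthAx <- c(0.11, 0.05, 0.035) * n * jit()
  mouthZ <- cz - 0.16 * n

  ax <- seq_len(n)
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))

  inEllipsoid <- function(ctr, semi) {
    ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
      ((Z - ctr[3]) / semi[3])^2 <= 1
  }
  # anterior (+y) head surface height at (x, z); NA outside the silhouette
  surfY <- function(x0, z0) {
    s <- 1 - ((x0 - cx) / headAx[1])^2 - ((z0 - cz) / headAx[3])^2
    cy + headAx[2] * sqrt(max(s, 0))
  }
  head0 <- inEllipsoid(c(cx, cy, cz), headAx)
  brain <- inEllipsoid(brainCenter, brainAx)
  if (any(brain & !head0)) stop("brain compartment escapes the head")
  regions <- list(
    nose = inEllipsoid(c(cx, surfY(cx, noseZ), noseZ), noseAx),
    left_eye = inEllipsoid(c(cx - eyeOff, surfY(cx - eyeOff, eyeZ), eyeZ),
                           rep(eyeR, 3)),
    right_eye = inEllipsoid(c(cx + eyeOff, surfY(cx + eyeOff, eyeZ), eyeZ),
                            rep(eyeR, 3)),
    mouth = inEllipsoid(c(cx, surfY(cx, mouthZ), mouthZ), mouthAx)
  )
  featureAny <- Reduce(`|`, regions)
  headAll <- head0 | featureAny
  if (any(brain & featureAny)) regions <- lapply(regions, function(r) r & !brain)

  vol <- array(0, c(n, n, n))
  vol[headAll] <- 0.55
  vol[featureAny & !brain] <- 0.70
  vol[brain] <- 0.85
  # scan-level acquisition noise, confined to the head so background stays 0
  set.seed(childSeed(spec$seed, 202L))
  nh <- sum(headAll)
  if (spec$noiseSd > 0)
    vol[headAll] <- pmin(pmax(vol[headAll] + rnorm(nh, 0, spec$noiseSd), 0.05), 1)

  # surface-inward removal order: outermost (farthest from head center) first
  ctr <- c(cx, cy, cz)
  d2 <- (X - ctr[1])^2 + ((Y - ctr[2]) / (headAx[2] / headAx[1]))^2 +
        (Z - ctr[3])^2
  featureVoxels <- lapply(regions, function(r) {
    idx <- which(r)
    idx[order(d2[idx], idx, decreasing = c(TRUE, FALSE), method = "radix")]
  })

  scan <- newScan(vol, scanId = spec$scanId, subjectId = spec$subjectId)
  new("HeadPhantom",
      scan = scan,
      headMask = new("VoxelMask", voxels = headAll, kind = "head",
                     sourceScanId = spec$scanId),
      brainMask = new("VoxelMask", voxels = brain, kind = "brain",
                      sourceScanId = spec$scanId),
      featureVoxels = featureVoxels,
      spec = spec)
}

#' Simulated defacing outcomes
#'
#' `defaceSimSpec()` parameterizes one simulated defacing run: per-feature
#' removal extents (1 = fully removed, 0 = untouched), a tiny global
#' additive intensity perturbation (emulating defacers that alter nearly
#' every voxel), a brain-clip fraction (emulating accidental brain-tissue
#' damage), and the method tag carried as a categorical feature.
#' `simulateDefacing()` applies the spec to a phantom: the global
#' perturbation is added first, then the requested fraction of each
#' feature's voxels is zeroed surface-inward, then the requested fraction
#' of brain voxels is zeroed. Deterministic given the seed.
#'
#' @param removal named numeric vector in [0,1] over nose, left_eye,
#'   right_eye, mouth.
#' @param globalPerturbation additive intensity applied to every voxel.
#' @param brainClip fraction of brain-mask voxels zeroed.
#' @param method one of "pydeface", "quickshear", "fsldeface", "mrideface".
#' @param seed seed for the brain-clip voxel draw.
#' @return a named parameter list.
#' @export
defaceSimSpec <- function(removal = c(nose = 1, left_eye = 1, right_eye = 1,
                                      mouth = 1),
                          globalPerturbation = 0, brainClip = 0,
                          method = c("pydeface", "quickshear", "fsldeface",
                                     "mrideface"),
                          seed = 1L) {
  method <- match.arg(method)
  removal <- removal[featureNames4()]
  stopifnot(!anyNA(removal), all(removal >= 0 & removal <= 1),
            globalPerturbation >= 0, brainClip >= 0, brainClip <= 1)
  list(removal = removal, globalPerturbation = globalPerturbation,
       brainClip = brainClip, method = method, seed = as.integer(seed))
}

#' @rdname defaceSimSpec
#' @param phantom a \code{\linkS4class{HeadPhantom}}.
#' @param sim a [defaceSimSpec()].
#' @return `simulateDefacing()` returns the defaced
#'   \code{\linkS4class{MRIScan}}.
#' @export
simulateDefacing <- function(phantom, sim = defaceSimSpec()) {
  stopifnot(is(phantom, "HeadPhantom"))
  vol <- phantom@scan@intensities
  if (sim$globalPerturbation > 0) vol <- vol + sim$globalPerturbation
  for (f in featureNames4()) {
    idx <- phantom@featureVoxels[[f]]
    nrem <- round(sim$removal[[f]] * length(idx))
    if (nrem > 0) vol[idx[seq_len(nrem)]] <- 0
  }
  if (sim$brainClip > 0) {
    bidx <- which(phantom@brainMask@voxels)
    nclip <- floor(sim$brainClip * length(bidx))
    if (nclip > 0) {
      set.seed(childSeed(sim$seed, 303L))
      vol[sample(bidx, nclip)] <- 0
    }
  }
  newScan(vol, affine = phantom@scan@affine,
          scanId = paste0(phantom@scan@scanId, "_", sim$method),
          subjectId = phantom@scan@subjectId)
}

#' Ground-truth label from a simulated defacing
#'
#' A feature counts as residual when its removal extent is below
#' `residualThreshold` (default 0.95). Under the strict criterion, defacing
#' succeeds (y = 0) only with zero residual features. Under the lenient
#' criterion a single residual feature is tolerated provided its removal
#' extent is at least `minimalResidual` (a "minimal trace"); anything more
#' is insufficient (y = 1).
#'
#' @param sim a [defaceSimSpec()].
#' @param rule a [groundTruthRule()].
#' @return 0 (successfully defaced) or 1 (insufficiently defaced).
#' @examples
#' ok <- defaceSimSpec()                       # everything removed
#' labelDefacing(ok, groundTruthRule("strict"))    # 0
#' part <- defaceSimSpec(removal = c(nose = 0.7, left_eye = 1,
#'                                   right_eye = 1, mouth = 1))
#' labelDefacing(part, groundTruthRule("strict"))  # 1
#' labelDefacing(part, groundTruthRule("lenient")) # 0
#' @export
labelDefacing <- function(sim, rule = groundTruthRule("lenient")) {
  resid <- sim$removal[sim$removal < rule$residualThreshold]
  if (rule$criterion == "strict") {
    as.integer(length(resid) > 0)
  } else {
    ok <- length(resid) == 0 ||
      (length(resid) == 1 && resid >= rule$minimalResidual)
    as.integer(!ok)
  }
}
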