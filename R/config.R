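#' Configuration objects
#'
#' `preprocessConfig()`, `similarityConfig()`, `cvConfig()` and
#' `groundTruthRule()` build the parameter lists used across the pipeline;
#' `qaConfig()` composes them into one run configuration that round-trips
#' losslessly through a YAML file via [writeConfig()] / [readConfig()].
#'
#' @param headThreshold intensity threshold on min-max normalized data above
#'   which a voxel counts as head tissue. Default 0.03.
#' @param alteredTolerance tolerance on the absolute original/defaced
#'   intensity difference below which a voxel does not count as altered.
#'   Default 0 (any nonzero difference counts).
#' @param canonicalOrientation axis convention all volumes are reoriented to
#'   before feature computation. Fixed to "RAS" (right/anterior/superior).
#' @return a named list of parameters.
#' @export
preprocessConfig <- function(headThreshold = 0.03, alteredTolerance = 0,
                             canonicalOrientation = "RAS") {
  stopifnot(headThreshold > 0, headThreshold < 1, alteredTolerance >= 0,
            identical(canonicalOrientation, "RAS"))
  list(headThreshold = headThreshold, alteredTolerance = alteredTolerance,
       canonicalOrientation = canonicalOrientation)
}

#' @rdname preprocessConfig
#' @param dynamicRange dynamic range L of the view images (they live in
#'   [0,1], so 1.0).
#' @param psnrCap PSNR value, in dB, reported for identical images (RMSE 0)
#'   so the feature table stays finite.
#' @param ssimK1,ssimK2 SSIM stabilization constants; C1=(K1 L)^2,
#'   C2=(K2 L)^2.
#' @param ssimSigma,ssimWindow Gaussian window sigma (px) and width for the
#'   local SSIM statistics.
#' @param fsimT1,fsimT2 FSIM contrast constants for the phase-congruency and
#'   gradient terms, on the conventional 8-bit scale (internally rescaled to
#'   `dynamicRange`).
#' @param fsimScales,fsimOrients log-Gabor filter-bank size for phase
#'   congruency.
#' @param aggregation how the five per-view metric values become one
#'   feature: "mean" (default) or "min".
#' @export
similarityConfig <- function(dynamicRange = 1.0, psnrCap = 100,
                             ssimK1 = 0.01, ssimK2 = 0.03,
                             ssimSigma = 1.5, ssimWindow = 11L,
                             fsimT1 = 0.85, fsimT2 = 160,
                             fsimScales = 4L, fsimOrients = 4L,
                             aggregation = c("mean", "min")) {
  aggregation <- match.arg(aggregation)
  stopifnot(dynamicRange > 0, psnrCap > 0, ssimK1 > 0, ssimK2 > 0,
            ssimSigma > 0, ssimWindow >= 3, fsimT1 > 0, fsimT2 > 0)
  list(dynamicRange = dynamicRange, psnrCap = psnrCap,
       ssimK1 = ssimK1, ssimK2 = ssimK2, ssimSigma = ssimSigma,
       ssimWindow = as.integer(ssimWindow), fsimT1 = fsimT1, fsimT2 = fsimT2,
       fsimScales = as.integer(fsimScales),
       fsimOrients = as.integer(fsimOrients), aggregation = aggregation)
}

#' @rdname preprocessConfig
#' @param outerFolds,innerFolds fold counts for the nested cross-validation
#'   (outer loop estimates generalization, inner loop tunes).
#' @param models subset of c("lr","mlp","rf","xgb").
#' @param permutationRepeats shuffles per feature for permutation
#'   importance.
#' @param corThreshold absolute Spearman correlation above which features
#'   form a redundancy cluster during selection.
#' @param importanceFloor minimum mean AUROC drop below which a feature is a
#'   removal candidate.
#' @param maxIterations cap on feature-selection iterations.
#' @export
cvConfig <- function(outerFolds = 5L, innerFolds = 3L,
                     models = c("lr", "mlp", "rf", "xgb"),
                     permutationRepeats = 10L,
                     corThreshold = 0.8, importanceFloor = 0.005,
                     maxIterations = 10L) {
  models <- match.arg(models, c("lr", "mlp", "rf", "xgb"), several.ok = TRUE)
  stopifnot(outerFolds >= 2, innerFolds >= 2, permutationRepeats >= 1,
            corThreshold > 0, corThreshold < 1)
  list(outerFolds = as.integer(outerFolds), innerFolds = as.integer(innerFolds),
       models = models, permutationRepeats = as.integer(permutationRepeats),
       corThreshold = corThreshold, importanceFloor = importanceFloor,
       maxIterations = as.integer(maxIterations))
}

#' @rdname preprocessConfig
#' @param criterion "strict" (success requires complete removal of all
#'   facial features) or "lenient" (tolerates a minimal residual trace of at
#'   most one feature).
#' @param residualThreshold removal extent below which a feature counts as
#'   residual. Default 0.95.
#' @param minimalResidual removal extent at or above which a single residual
#'   still counts as "minimal" under the lenient criterion. Default 0.5.
#' @export
groundTruthRule <- function(criterion = c("strict", "lenient"),
                            residualThreshold = 0.95, minimalResidual = 0.5) {
  criterion <- match.arg(criterion)
  stopifnot(residualThreshold > 0, residualThreshold <= 1,
            minimalResidual >= 0, minimalResidual <= residualThreshold)
  list(criterion = criterion, residualThreshold = residualThreshold,
       minimalResidual = minimalResidual)
}

#' @rdname preprocessConfig
#' @param preprocess,similarity,cv,rule component configurations.
#' @param resolution view-image side length in pixels (default 256).
#' @param seed master seed; all randomness in a run derives from it.
#' @export
qaConfig <- function(preprocess = preprocessConfig(),
                     similarity = similarityConfig(),
                     cv = cvConfig(),
                     rule = groundTruthRule("lenient"),
                     resolution = 256L, seed = 1L) {
  stopifnot(resolution >= 16)
  list(preprocess = preprocess, similarity = similarity, cv = cv,
       rule = rule, resolution = as.integer(resolution),
       seed = as.integer(seed))
}

#' @rdname preprocessConfig
#' @param config a configuration list from [qaConfig()].
#' @param path file path for the YAML configuration.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname preprocessConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  # rebuild through the constructors so types and defaults are enforced
  qaConfig(
    preprocess = do.call(preprocessConfig, raw$preprocess),
    similarity = do.call(similarityConfig, raw$similarity),
    cv = do.call(cvConfig, raw$cv),
    rule = do.call(groundTruthRule, raw$rule),
    resolution = raw$resolution, seed = raw$seed
  )
}

# derive a child seed from a master seed; keeps values in 32-bit range
childSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629)
}
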