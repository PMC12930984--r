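#' MRIScan: a 3D intensity volume with spatial metadata
#'
#' Holds one scan's voxel grid (non-negative intensities in arbitrary
#' scanner units), its 4x4 voxel-to-world affine, and identifiers. All
#' feature computations assume scans have been reoriented to the canonical
#' RAS axis order (see \code{\link{readScan}}).
#'
#' @slot intensities 3D numeric array, finite values.
#' @slot affine 4x4 invertible voxel-to-world transform.
#' @slot scanId scan identifier.
#' @slot subjectId subject (group) identifier.
#' @export
setClass("MRIScan",
  representation(
    intensities = "array",
    affine = "matrix",
    scanId = "character",
    subjectId = "character"
  )
)

setValidity("MRIScan", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "intensities must be a 3D array with each axis length >= 1")
  if (!all(is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "affine must be invertible")
  if (length(object@scanId) != 1L) msg <- c(msg, "scanId must be length 1")
  if (length(msg)) msg else TRUE
})

#' VoxelMask: a boolean 3D grid aligned to an MRIScan
#'
#' @slot voxels logical 3D array, same grid shape as its scan.
#' @slot kind "head" or "brain".
#' @slot sourceScanId id of the scan the mask belongs to.
#' @export
setClass("VoxelMask",
  representation(
    voxels = "array",
    kind = "character",
    sourceScanId = "character"
  )
)

setValidity("VoxelMask", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L || !is.logical(object@voxels))
    msg <- c(msg, "voxels must be a logical 3D array")
  if (!object@kind %in% c("head", "brain"))
    msg <- c(msg, "kind must be 'head' or 'brain'")
  if (length(msg)) msg else TRUE
})

#' ViewSet: five standardized 2D surface renderings of one scan
#'
#' The five canonical perspectives are frontal, left/right profile, and
#' left/right 45-degree views, at azimuths 0, -90, +90, -45, +45 degrees
#' about the superior axis relative to the facing (anterior) direction.
#'
#' @slot images named list of numeric matrices with values in [0,1];
#'   background (no surface hit) is 0.
#' @slot azimuths named numeric vector of view azimuths in degrees.
#' @slot resolution image side length in pixels.
#' @slot scanId id of the rendered scan.
#' @export
setClass("ViewSet",
  representation(
    images = "list",
    azimuths = "numeric",
    resolution = "integer",
    scanId = "character"
  )
)

setValidity("ViewSet", function(object) {
  msg <- character()
  if (!identical(names(object@images), viewNames()))
    msg <- c(msg, "images must be named frontal, left_profile, right_profile, left_45, right_45 in order")
  ok <- vapply(object@images, function(im) {
    is.matrix(im) && all(is.finite(im)) && min(im) >= 0 && max(im) <= 1
  }, logical(1))
  if (!all(ok)) msg <- c(msg, "all view images must be matrices with values in [0,1]")
  if (object@resolution < 16L) msg <- c(msg, "resolution must be >= 16")
  if (length(msg)) msg else TRUE
})

#' HeadPhantom: a synthetic head scan with masks and facial-feature geometry
#'
#' Produced by \code{\link{generatePhantom}}. Besides the scan and its
#' head/brain masks it records, for each facial feature, the linear voxel
#' indices ordered surface-inward, which \code{\link{simulateDefacing}} uses
#' to remove a controlled fraction of each feature.
#'
#' @slot scan the phantom \code{\linkS4class{MRIScan}}.
#' @slot headMask,brainMask \code{\linkS4class{VoxelMask}} objects; the brain
#'   mask is strictly inside the head mask.
#' @slot featureVoxels named list (nose, left_eye, right_eye, mouth) of
#'   integer voxel indices, outermost first.
#' @slot spec the generating parameter list (geometry, noise, seed).
#' @export
setClass("HeadPhantom",
  representation(
    scan = "MRIScan",
    headMask = "VoxelMask",
    brainMask = "VoxelMask",
    featureVoxels = "list",
    spec = "list"
  )
)

setValidity("HeadPhantom", function(object) {
  msg <- character()
  h <- object@headMask@voxels; b <- object@brainMask@voxels
  if (!identical(dim(h), dim(object@scan@intensities)))
    msg <- c(msg, "head mask shape must match the scan")
  if (any(b & !h)) msg <- c(msg, "brain mask must lie inside the head mask")
  if (!all(c("nose", "left_eye", "right_eye", "mouth") %in% names(object@featureVoxels)))
    msg <- c(msg, "featureVoxels must cover nose, left_eye, right_eye, mouth")
  if (length(msg)) msg else TRUE
})

#' NestedCVResult: nested cross-validation report
#'
#' Per-outer-fold and aggregated classification metrics for each model,
#' plus permutation feature importances averaged across outer folds.
#'
#' @slot foldMetrics data.frame with one row per model x outer fold
#'   (accuracy, sensitivity, specificity, precision, auroc).
#' @slot summary data.frame of per-model mean and sd over outer folds.
#' @slot importance data.frame of mean permutation importances
#'   (AUROC drop) per model and feature; empty if not computed.
#' @slot folds integer vector of outer-fold assignment per sample.
#' @slot config the \code{\link{cvConfig}} used.
#' @slot seed master seed.
#' @export
setClass("NestedCVResult",
  representation(
    foldMetrics = "data.frame",
    summary = "data.frame",
    importance = "data.frame",
    folds = "integer",
    config = "list",
    seed = "integer"
  )
)

#' DefacingModel: a trained classifier bundle
#'
#' Couples a fitted model with its feature schema, scaling parameters and
#' configuration snapshot so that predictions reject mismatched inputs.
#'
#' @slot fit the fitted model object.
#' @slot modelType one of "lr", "mlp", "rf", "xgb".
#' @slot featureNames feature schema (column names, in order).
#' @slot scaling list with center/scale vectors (NULL for tree models).
#' @slot threshold decision threshold on the score.
#' @slot config configuration snapshot.
#' @slot seed training seed.
#' @export
setClass("DefacingModel",
  representation(
    fit = "ANY",
    modelType = "character",
    featureNames = "character",
    scaling = "ANY",
    threshold = "numeric",
    config = "list",
    seed = "integer"
  )
)
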