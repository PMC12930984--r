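#' @rdname MRIScan-class
#' @param object,x an object.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname MRIScan-class
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname MRIScan-class
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))

#' @rdname MRIScan-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname VoxelMask-class
#' @export
setGeneric("maskKind", function(x) standardGeneric("maskKind"))

#' @rdname VoxelMask-class
#' @export
setGeneric("maskCount", function(x) standardGeneric("maskCount"))

#' @rdname ViewSet-class
#' @export
setGeneric("viewImages", function(x) standardGeneric("viewImages"))

#' @rdname NestedCVResult-class
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname NestedCVResult-class
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))

#' @rdname NestedCVResult-class
#' @export
setGeneric("featureImportance", function(x) standardGeneric("featureImportance"))

setMethod("voxelData", "MRIScan", function(x) x@intensities)
setMethod("voxelData", "VoxelMask", function(x) x@voxels)
setMethod("affineMatrix", "MRIScan", function(x) x@affine)
setMethod("scanId", "MRIScan", function(x) x@scanId)
setMethod("scanId", "VoxelMask", function(x) x@sourceScanId)
setMethod("scanId", "ViewSet", function(x) x@scanId)
setMethod("subjectId", "MRIScan", function(x) x@subjectId)
setMethod("maskKind", "VoxelMask", function(x) x@kind)
setMethod("maskCount", "VoxelMask", function(x) sum(x@voxels))
setMethod("viewImages", "ViewSet", function(x) x@images)
setMethod("foldMetrics", "NestedCVResult", function(x) x@foldMetrics)
setMethod("cvSummary", "NestedCVResult", function(x) x@summary)
setMethod("featureImportance", "NestedCVResult", function(x) x@importance)

setMethod("show", "MRIScan", function(object) {
  d <- dim(object@intensities)
  cat("MRIScan", object@scanId,
      sprintf("(subject %s)\n", object@subjectId),
      sprintf("  grid %d x %d x %d, intensity range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(object@intensities), max(object@intensities)))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VoxelMask (%s) for scan %s: %d / %d voxels\n",
              object@kind, object@sourceScanId, sum(object@voxels), prod(d)))
})

setMethod("show", "ViewSet", function(object) {
  cat(sprintf("ViewSet for scan %s: %d views at %d x %d px\n",
              object@scanId, length(object@images),
              object@resolution, object@resolution))
})

setMethod("show", "HeadPhantom", function(object) {
  cat(sprintf("HeadPhantom %s (subject %s): head %d, brain %d voxels, BHR %.3f\n",
              object@scan@scanId, object@scan@subjectId,
              sum(object@headMask@voxels), sum(object@brainMask@voxels),
              sum(object@brainMask@voxels) / sum(object@headMask@voxels)))
})

setMethod("show", "NestedCVResult", function(object) {
  cat(sprintf("NestedCVResult: %d outer folds, seed %d\n",
              max(object@folds), object@seed))
  print(object@summary, digits = 3)
})

setMethod("show", "DefacingModel", function(object) {
  cat(sprintf("DefacingModel (%s), %d features, threshold %.2f\n",
              object@modelType, length(object@featureNames), object@threshold))
})
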