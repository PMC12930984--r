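#' Volumetric impact measures of defacing
#'
#' Quantify how a defacing operation changed a scan, relative to a region
#' mask. `impactedVoxels()` is the percentage of region voxels whose
#' absolute intensity difference exceeds `tolerance`; `removedVoxels()` is
#' the percentage of region voxels that were nonzero in the original and are
#' exactly zero in the defaced scan; `brainImpact()` applies both with the
#' brain mask as region and denominator; `brainToHeadRatio()` is the ratio
#' of brain-mask to head-mask voxel counts (an anomaly indicator for mask
#' quality). Differences are computed on the raw, orientation-aligned
#' intensities; the head mask itself comes from the normalized original
#' scan, so the denominators are defacing-invariant.
#'
#' @param orig,defaced \code{\linkS4class{MRIScan}} objects on the same
#'   grid.
#' @param region a nonempty \code{\linkS4class{VoxelMask}} (head or brain).
#' @param tolerance absolute difference below which a voxel is not counted
#'   as altered (default 0: any change counts).
#' @return a percentage in [0,100] (`brainImpact()` returns a named vector
#'   of altered and removed percentages; `brainToHeadRatio()` a ratio).
#' @examples
#' a <- array(1, c(3, 3, 3)); b <- a; b[1:4] <- 0
#' orig <- newScan(a); def <- newScan(b)
#' m <- new("VoxelMask", voxels = array(TRUE, dim(a)), kind = "head",
#'          sourceScanId = "scan")
#' impactedVoxels(orig, def, m)   # 4/27 altered
#' removedVoxels(orig, def, m)    # same 4 voxels zeroed
#' @export
impactedVoxels <- function(orig, defaced, region, tolerance = 0) {
  dif <- pairDiff(orig, defaced, region)
  100 * sum(dif$delta > tolerance) / dif$n
}

#' @rdname impactedVoxels
#' @export
removedVoxels <- function(orig, defaced, region) {
  dif <- pairDiff(orig, defaced, region)
  100 * sum(dif$o != 0 & dif$d == 0) / dif$n
}

#' @rdname impactedVoxels
#' @param brain a nonempty brain \code{\linkS4class{VoxelMask}}.
#' @export
brainImpact <- function(orig, defaced, brain, tolerance = 0) {
  if (brain@kind != "brain")
    warning("brainImpact called with a '", brain@kind, "' mask")
  c(altered = impactedVoxels(orig, defaced, brain, tolerance),
    removed = removedVoxels(orig, defaced, brain))
}

#' @rdname impactedVoxels
#' @param head a nonempty head \code{\linkS4class{VoxelMask}}.
#' @export
brainToHeadRatio <- function(brain, head) {
  nh <- sum(head@voxels)
  if (nh == 0) stop("empty head mask: brain-to-head ratio undefined")
  sum(brain@voxels) / nh
}

#' @rdname impactedVoxels
#' @param config a [preprocessConfig()] supplying the altered-voxel
#'   tolerance.
#' @return `volumetricFeatures()` returns a one-row data.frame with columns
#'   head_impacted_pct, head_removed_pct, brain_impacted_pct,
#'   brain_removed_pct, bhr.
#' @export
volumetricFeatures <- function(orig, defaced, head, brain,
                               config = preprocessConfig()) {
  eps <- config$alteredTolerance
  bi <- brainImpact(orig, defaced, brain, eps)
  data.frame(
    head_impacted_pct = impactedVoxels(orig, defaced, head, eps),
    head_removed_pct = removedVoxels(orig, defaced, head),
    brain_impacted_pct = unname(bi["altered"]),
    brain_removed_pct = unname(bi["removed"]),
    bhr = brainToHeadRatio(brain, head)
  )
}

pairDiff <- function(orig, defaced, region) {
  stopifnot(is(orig, "MRIScan"), is(defaced, "MRIScan"),
            is(region, "VoxelMask"))
  if (!identical(dim(orig@intensities), dim(defaced@intensities)))
    stop("original and defaced scans must share grid shape (",
         paste(dim(orig@intensities), collapse = "x"), " vs ",
         paste(dim(defaced@intensities), collapse = "x"), ")")
  if (!identical(dim(orig@intensities), dim(region@voxels)))
    stop("mask grid shape does not match the scans")
  idx <- region@voxels
  n <- sum(idx)
  if (n == 0) stop("empty ", region@kind, " mask: percentage undefined")
  o <- orig@intensities[idx]
  d <- defaced@intensities[idx]
  list(o = o, d = d, delta = abs(o - d), n = n)
}
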