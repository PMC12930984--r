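#' Read a NIfTI volume as an MRIScan in canonical orientation
#'
#' Loads a single-volume NIfTI file and reorients the grid to the canonical
#' RAS (right/anterior/superior) axis order, so that the anterior (facing)
#' direction is well defined for view rendering. Intensities are unchanged
#' apart from the axis permutation/flips implied by the stored affine.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param scanId,subjectId identifiers attached to the scan; default to the
#'   file base name.
#' @return an \code{\linkS4class{MRIScan}}.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeScan(newScan(array(runif(27), c(3, 3, 3)), scanId = "s1"), f)
#' readScan(f)
#' @export
readScan <- function(path, scanId = NULL, subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), d[1:3]), reference = img)
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a single 3D volume, got ", length(d), " dimensions: ", path)
  xf <- RNifti::xform(img)
  if (abs(det(xf)) < .Machine$double.eps)
    stop("non-invertible affine in ", path)
  ori <- RNifti::orientation(img)
  if (!identical(ori, "RAS")) RNifti::orientation(img) <- "RAS"
  base <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (is.null(scanId)) scanId <- base
  if (is.null(subjectId)) subjectId <- base
  new("MRIScan",
      intensities = array(as.double(img), dim(img)),
      affine = unclass(RNifti::xform(img))[1:4, 1:4],
      scanId = scanId, subjectId = subjectId)
}

#' @rdname readScan
#' @param intensities 3D numeric array.
#' @param affine 4x4 voxel-to-world transform (default identity, which is
#'   already RAS).
#' @export
newScan <- function(intensities, affine = diag(4), scanId = "scan",
                    subjectId = scanId) {
  new("MRIScan", intensities = array(as.double(intensities), dim(intensities)),
      affine = affine, scanId = scanId, subjectId = subjectId)
}

#' @rdname readScan
#' @param x an \code{\linkS4class{MRIScan}} or \code{\linkS4class{VoxelMask}}
#'   to write. Masks are stored as 0/1 integer volumes.
#' @export
writeScan <- function(x, path) {
  if (is(x, "VoxelMask")) {
    arr <- array(as.integer(x@voxels), dim(x@voxels))
    img <- RNifti::asNifti(arr, datatype = "uint8")
    RNifti::qform(img) <- structure(diag(4), code = 2L)
  } else {
    stopifnot(is(x, "MRIScan"))
    img <- RNifti::asNifti(x@intensities, datatype = "double")
    RNifti::qform(img) <- structure(x@affine, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname readScan
#' @param kind mask kind, "head" or "brain", for [readMask()].
#' @export
readMask <- function(path, kind = c("head", "brain"), scanId = NULL) {
  kind <- match.arg(kind)
  s <- readScan(path, scanId = scanId)
  new("VoxelMask", voxels = array(s@intensities > 0.5, dim(s@intensities)),
      kind = kind, sourceScanId = s@scanId)
}

#' Min-max normalize scan intensities to [0,1]
#'
#' Maps intensities through (x - min) / (max - min). A constant volume
#' normalizes to all zeros rather than erroring, so degenerate inputs flow
#' through with empty head masks.
#'
#' @param scan an \code{\linkS4class{MRIScan}}.
#' @return the scan with normalized intensities.
#' @export
normalizeScan <- function(scan) {
  stopifnot(is(scan, "MRIScan"))
  x <- scan@intensities
  if (!all(is.finite(x))) stop("non-finite intensities in ", scan@scanId)
  rng <- range(x)
  if (rng[2] > rng[1]) {
    scan@intensities <- (x - rng[1]) / (rng[2] - rng[1])
  } else {
    scan@intensities <- array(0, dim(x))
  }
  scan
}

#' Derive the head mask by intensity thresholding
#'
#' Marks voxels whose normalized intensity exceeds the head threshold
#' (default 0.03), removing low-intensity background voxels.
#'
#' @param scan a normalized \code{\linkS4class{MRIScan}} (values in [0,1]).
#' @param config a [preprocessConfig()].
#' @return a head \code{\linkS4class{VoxelMask}}.
#' @export
headMask <- function(scan, config = preprocessConfig()) {
  stopifnot(is(scan, "MRIScan"))
  x <- scan@intensities
  if (min(x) < 0 || max(x) > 1)
    stop("headMask expects normalized intensities in [0,1]; call normalizeScan() first")
  new("VoxelMask", voxels = array(x > config$headThreshold, dim(x)),
      kind = "head", sourceScanId = scan@scanId)
}
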