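# Five standardized surface views rendered by orthographic first-hit ray
# casting. The facing (anterior) direction in canonical RAS space is +y;
# azimuths rotate the camera about the superior (+z) axis.

viewNames <- function() c("frontal", "left_profile", "right_profile",
                          "left_45", "right_45")

viewAzimuths <- function() {
  c(frontal = 0, left_profile = -90, right_profile = 90,
    left_45 = -45, right_45 = 45)
}

#' Specification of one standardized view
#'
#' @param name one of frontal, left_profile, right_profile, left_45,
#'   right_45; fixes the azimuth (0, -90, +90, -45, +45 degrees).
#' @param resolution output image side length in pixels (>= 16).
#' @return a list with name, azimuth and resolution.
#' @export
viewSpec <- function(name = viewNames(), resolution = 256L) {
  name <- match.arg(name)
  stopifnot(resolution >= 16)
  list(name = name, azimuth = unname(viewAzimuths()[name]),
       resolution = as.integer(resolution))
}

# exact-direction camera basis for an azimuth (degrees about +z, 0 = facing
# +y / anterior). Uses sinpi/cospi so profile views are exact.
viewBasis <- function(azimuth) {
  t <- azimuth / 180
  cam <- c(sinpi(t), cospi(t), 0)      # camera sits on this side
  dir <- -cam                          # rays travel into the volume
  up <- c(0, 0, 1)
  u <- c(up[2] * dir[3] - up[3] * dir[2],
         up[3] * dir[1] - up[1] * dir[3],
         up[1] * dir[2] - up[2] * dir[1])
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  list(dir = dir, u = u, v = v)
}

#' Render a standardized surface view of a masked volume
#'
#' Orthographic first-hit ray casting: rays parallel to the view direction
#' traverse the grid front-to-back at half-voxel steps; each pixel takes the
#' intensity of the first head-mask voxel hit, 0 (background) if none. The
#' image plane is scaled to the volume bounding box with square pixels
#' (letterboxed), so corresponding views of a scan pair are directly
#' comparable. Rendering is deterministic.
#'
#' @param scan a normalized \code{\linkS4class{MRIScan}}.
#' @param mask the scan's head \code{\linkS4class{VoxelMask}}. An empty mask
#'   yields an all-background image.
#' @param spec a [viewSpec()].
#' @return a numeric `resolution x resolution` matrix in [0,1].
#' @export
renderView <- function(scan, mask, spec = viewSpec("frontal")) {
  stopifnot(is(scan, "MRIScan"), is(mask, "VoxelMask"))
  if (!identical(dim(scan@intensities), dim(mask@voxels)))
    stop("mask grid shape does not match the scan")
  d <- dim(scan@intensities)
  A <- scan@affine[1:3, 1:3]
  Ainv <- solve(A)
  basis <- viewBasis(spec$azimuth)
  # voxel-space vectors per unit world length
  dirVox <- as.vector(Ainv %*% basis$dir)
  uVox <- as.vector(Ainv %*% basis$u)
  vVox <- as.vector(Ainv %*% basis$v)
  centerVox <- (d - 1) / 2
  # world-space half extent of the grid bounding box projected on the plane
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5), c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  cw <- t(A %*% (t(corners) - centerVox))
  halfExtent <- max(abs(cw %*% basis$u), abs(cw %*% basis$v))
  voxelEdges <- sqrt(colSums(A^2))
  step <- min(voxelEdges) / 2
  tMax <- 2 * sqrt(max(rowSums(cw^2))) + 2 * step
  raycast_view_cpp(as.double(scan@intensities),
                   as.integer(mask@voxels), as.integer(d),
                   dirVox, uVox, vVox, centerVox,
                   halfExtent, spec$resolution, step, tMax)
}

#' @rdname renderView
#' @param resolution pixels per image side for all five views.
#' @return `renderAllViews()` returns a \code{\linkS4class{ViewSet}} holding
#'   the five canonical views in fixed order.
#' @export
renderAllViews <- function(scan, mask, resolution = 256L) {
  az <- viewAzimuths()
  images <- lapply(names(az), function(nm)
    renderView(scan, mask, viewSpec(nm, resolution)))
  names(images) <- names(az)
  new("ViewSet", images = images, azimuths = az,
      resolution = as.integer(resolution), scanId = scan@scanId)
}

#' Export a view set as 8-bit grayscale PNG files
#'
#' Pixel values are `round(255 * value)`; metric computation always uses
#' the float images, PNG export exists for human review.
#'
#' @param views a \code{\linkS4class{ViewSet}}.
#' @param dir output directory; files are named `<scanId>_<view>.png`.
#' @return invisibly, the written file paths.
#' @export
writeViewPNGs <- function(views, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(views@images), function(nm) {
    p <- file.path(dir, paste0(views@scanId, "_", nm, ".png"))
    png::writePNG(round(255 * views@images[[nm]]) / 255, p)
    p
  }, character(1))
  invisible(paths)
}
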