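#' Construct an image grid
#'
#' @param shape integer extents per axis (length 2 or 3).
#' @param voxelSize voxel size in mm, scalar (isotropic) or per axis.
#' @param origin mm coordinate of the first voxel centre per axis; the
#'   default centres the grid on the scanner axis (iso-centre at 0 mm).
#' @return an [ImageGrid-class].
#' @examples
#' g <- imageGrid(c(128, 128), voxelSize = 2.09)
#' fovExtent(g)
#' @export
imageGrid <- function(shape, voxelSize, origin = NULL) {
  shape <- as.integer(shape)
  nd <- length(shape)
  voxelSize <- rep_len(as.numeric(voxelSize), nd)
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxelSize
  new("ImageGrid", shape = shape, voxelSize = voxelSize,
      origin = as.numeric(rep_len(origin, nd)))
}

#' Physical field-of-view extent of a grid, in mm per axis
#' @param grid an [ImageGrid-class].
#' @return numeric vector, shape * voxelSize.
#' @export
fovExtent <- function(grid) grid@shape * grid@voxelSize

#' Voxel-centre coordinates along one axis, in mm
#' @param grid an [ImageGrid-class].
#' @param axis axis index.
#' @return numeric vector of voxel-centre coordinates.
#' @export
voxelCenters <- function(grid, axis)
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1) * grid@voxelSize[axis]

#' Construct a volume image
#'
#' @param values numeric array or scalar (recycled over the grid).
#' @param grid the [ImageGrid-class] the values live on.
#' @return a [VolumeImage-class].
#' @export
volumeImage <- function(values, grid) {
  if (length(values) == 1L) values <- array(values, dim = grid@shape)
  if (is.null(dim(values))) dim(values) <- grid@shape
  storage.mode(values) <- "double"
  new("VolumeImage", grid = grid, values = values)
}

#' Construct a parallel-beam sinogram geometry
#'
#' @param nRadial number of radial bins.
#' @param nAngles number of uniformly spaced angles over [0, pi).
#' @param radialBinSize radial bin size in mm (default 2.045, the clinical
#'   PET-MR sinogram sampling).
#' @param nPlanes number of independent axial planes (1 for 2-D).
#' @return a [SinogramGeometry-class].
#' @export
sinogramGeometry <- function(nRadial, nAngles, radialBinSize = 2.045,
                             nPlanes = 1L) {
  new("SinogramGeometry", nRadial = as.integer(nRadial),
      nAngles = as.integer(nAngles), radialBinSize = as.numeric(radialBinSize),
      nPlanes = as.integer(nPlanes))
}

#' Construct a sinogram
#'
#' @param values numeric array (nRadial x nAngles [x nPlanes]) or scalar.
#' @param geometry a [SinogramGeometry-class].
#' @param role data role; see [Sinogram-class].
#' @return a [Sinogram-class].
#' @export
sinogram <- function(values, geometry, role = "generic") {
  d <- c(geometry@nRadial, geometry@nAngles)
  if (geometry@nPlanes > 1L) d <- c(d, geometry@nPlanes)
  if (length(values) == 1L) values <- array(values, dim = d)
  if (is.null(dim(values))) dim(values) <- d
  storage.mode(values) <- "double"
  new("Sinogram", geometry = geometry, values = values, role = role)
}

#' Radial bin-centre offsets in mm for a sinogram geometry
#' @param geometry a [SinogramGeometry-class].
#' @return numeric vector of signed radial offsets, centred on the axis.
#' @export
radialOffsets <- function(geometry)
  (seq_len(geometry@nRadial) - (geometry@nRadial + 1) / 2) * geometry@radialBinSize

#' Projection angles in radians for a sinogram geometry
#' @param geometry a [SinogramGeometry-class].
#' @return numeric vector of angles in [0, pi).
#' @export
projectionAngles <- function(geometry)
  (seq_len(geometry@nAngles) - 1) * pi / geometry@nAngles

## ---- accessors ----

#' @describeIn values values of a VolumeImage
#' @export
setMethod("values", "VolumeImage", function(x) x@values)

#' @describeIn values values of a Sinogram
#' @export
setMethod("values", "Sinogram", function(x) x@values)

#' @rdname values
#' @export
setMethod("values<-", "VolumeImage", function(x, value) {
  v <- x@values; v[] <- value; x@values <- v; validObject(x); x
})

#' @rdname values
#' @export
setMethod("values<-", "Sinogram", function(x, value) {
  v <- x@values; v[] <- value; x@values <- v; validObject(x); x
})

#' Grid of a VolumeImage
#' @param image a [VolumeImage-class].
#' @return the [ImageGrid-class].
#' @export
imageGridOf <- function(image) image@grid

#' Geometry of a Sinogram
#' @param sino a [Sinogram-class].
#' @return the [SinogramGeometry-class].
#' @export
sinogramGeometryOf <- function(sino) sino@geometry

## ---- show methods ----

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels, %s mm, FOV %s mm\n",
              paste(object@shape, collapse = " x "),
              paste(signif(object@voxelSize, 4), collapse = " x "),
              paste(signif(fovExtent(object), 4), collapse = " x ")))
})

setMethod("show", "VolumeImage", function(object) {
  cat(sprintf("VolumeImage on %s grid (%s mm voxels); range [%.4g, %.4g]\n",
              paste(object@grid@shape, collapse = "x"),
              paste(signif(object@grid@voxelSize, 4), collapse = "x"),
              min(object@values), max(object@values)))
})

setMethod("show", "SinogramGeometry", function(object) {
  cat(sprintf(
    "SinogramGeometry: %d radial bins x %.4g mm, %d angles over [0, pi), %d plane(s)\n",
    object@nRadial, object@radialBinSize, object@nAngles, object@nPlanes))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram [%s]: %d x %d bins, total %.6g\n", object@role,
              object@geometry@nRadial, object@geometry@nAngles,
              sum(object@values)))
})

setMethod("show", "SystemModel", function(object) {
  cat("SystemModel:", paste(object@components, collapse = " o "), "\n")
  cat("  projection grid: "); show(object@grid)
  if (!identical(object@reconGrid@shape, object@grid@shape) ||
      !identical(object@reconGrid@voxelSize, object@grid@voxelSize)) {
    cat("  reconstruction grid: "); show(object@reconGrid)
  }
  cat("  "); show(object@geometry)
})

setMethod("show", "PriorModel", function(object) {
  cat(sprintf(
    "PriorModel: %d-neighbour smoothed Lange prior, delta = %.4g, beta = %.4g\n",
    nrow(object@neighborhood@offsets), object@delta, object@beta))
  cat(sprintf("  mean selected neighbours per voxel: %.2f\n",
              mean(rowSums(object@w))))
})

setMethod("show", "PhantomStudy", function(object) {
  cat(sprintf("PhantomStudy (seed %d): %.4g prompts (%.1f%% randoms, %.1f%% scatter fraction)\n",
              object@seed, sum(object@prompts@values),
              100 * sum(object@randoms@values) / max(sum(object@prompts@values), 1),
              100 * sum(object@scatter@values) /
                max(sum(object@trues@values) + sum(object@scatter@values), 1)))
})
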