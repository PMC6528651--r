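#' @import methods
#' @importFrom stats rpois rnorm sd convolve fft
#' @importFrom utils write.csv read.csv modifyList
NULL

#' ImageGrid: a voxel lattice with physical spacing
#'
#' Describes a 2-D or 3-D voxel lattice: integer extents per axis, physical
#' voxel sizes in mm, and the mm coordinate of the first voxel centre. All
#' physical geometry in the package (ray tracing, interpolation between
#' grids, PSF kernels in mm) is derived from this description.
#'
#' @slot shape integer extents per axis (length 2 or 3), each >= 1.
#' @slot voxelSize mm per axis, strictly positive.
#' @slot origin mm coordinate of the centre of the first voxel per axis.
#'
#' @seealso [imageGrid()], [VolumeImage-class]
#' @export
setClass("ImageGrid",
  representation(shape = "integer", voxelSize = "numeric", origin = "numeric"))

setValidity("ImageGrid", function(object) {
  nd <- length(object@shape)
  if (!nd %in% c(2L, 3L)) return("shape must have length 2 or 3")
  if (length(object@voxelSize) != nd || length(object@origin) != nd)
    return("shape, voxelSize and origin must have equal length")
  if (any(object@shape < 1L)) return("all shape entries must be >= 1")
  if (any(!is.finite(object@voxelSize)) || any(object@voxelSize <= 0))
    return("voxel sizes must be strictly positive and finite")
  if (any(!is.finite(object@origin))) return("origin must be finite")
  TRUE
})

#' VolumeImage: a scalar field on an ImageGrid
#'
#' Couples a numeric array (activity, attenuation in 1/mm, anatomical
#' intensity, or integer tissue label) to the [ImageGrid-class] it lives on.
#'
#' @slot grid the [ImageGrid-class].
#' @slot values numeric array whose dim equals the grid shape.
#'
#' @export
setClass("VolumeImage",
  representation(grid = "ImageGrid", values = "array"))

setValidity("VolumeImage", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    return("values array dimensions must equal grid shape")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' SinogramGeometry: parallel-beam radial/angular sampling
#'
#' Idealized parallel-beam line-of-response sampling: `nRadial` radial bins
#' of `radialBinSize` mm centred on the scanner axis, `nAngles` projection
#' angles uniformly spaced over [0, pi), and `nPlanes` independent axial
#' planes (1 for 2-D). Rays falling entirely outside the image field of
#' view contribute zero and are handled through the sensitivity image.
#'
#' @slot nRadial number of radial bins.
#' @slot radialBinSize radial bin size in mm (scanner default 2.045 mm).
#' @slot nAngles number of projection angles over [0, pi).
#' @slot nPlanes number of axial planes (1 for a single slice).
#'
#' @export
setClass("SinogramGeometry",
  representation(nRadial = "integer", radialBinSize = "numeric",
                 nAngles = "integer", nPlanes = "integer"))

setValidity("SinogramGeometry", function(object) {
  if (object@nRadial < 1L || object@nAngles < 1L || object@nPlanes < 1L)
    return("nRadial, nAngles and nPlanes must be >= 1")
  if (!is.finite(object@radialBinSize) || object@radialBinSize <= 0)
    return("radialBinSize must be strictly positive")
  TRUE
})

.sinogramRoles <- c("prompts", "trues", "randoms", "scatter",
                    "attenuation_factors", "normalization_factors",
                    "sensitivity", "generic")

#' Sinogram: counts or factors on a SinogramGeometry
#'
#' @slot geometry the [SinogramGeometry-class].
#' @slot values numeric array (nRadial x nAngles [x nPlanes]).
#' @slot role one of prompts, trues, randoms, scatter, attenuation_factors,
#'   normalization_factors, sensitivity, generic. Count- and factor-type
#'   sinograms are validated non-negative.
#'
#' @export
setClass("Sinogram",
  representation(geometry = "SinogramGeometry", values = "array",
                 role = "character"))

setValidity("Sinogram", function(object) {
  g <- object@geometry
  want <- c(g@nRadial, g@nAngles)
  if (g@nPlanes > 1L) want <- c(want, g@nPlanes)
  d <- dim(object@values)
  if (length(d) == 3L && d[3] == 1L) d <- d[1:2]
  if (!identical(as.integer(d), as.integer(want)))
    return("values dimensions must match geometry (nRadial x nAngles [x nPlanes])")
  if (length(object@role) != 1L || !object@role %in% .sinogramRoles)
    return(paste("role must be one of:", paste(.sinogramRoles, collapse = ", ")))
  if (object@role %in% c("prompts", "trues", "randoms", "scatter",
                         "attenuation_factors", "normalization_factors") &&
      any(object@values < 0))
    return("count-type and factor-type sinograms must be non-negative")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' SystemModel: the forward/backward projection pair
#'
#' Encapsulates the linear system operator A and its exact adjoint A'. The
#' forward direction is mult * X_lr(D(blur(theta))): an optional isotropic
#' Gaussian PSF applied in image space on the reconstruction grid, an
#' optional trilinear down-sampling operator D from the (finer)
#' reconstruction grid to the projection grid, the Siddon ray-tracing
#' projector X_lr on the projection grid, and an optional multiplicative
#' correction sinogram (attenuation x normalization). The backward
#' direction applies the transposes in reverse order, so the pair is
#' matched by construction.
#'
#' @slot grid projection-side [ImageGrid-class] (the "standard" grid).
#' @slot reconGrid the grid reconstruction is performed on (equal to
#'   `grid`, or finer in high-resolution / MRvox mode).
#' @slot geometry the [SinogramGeometry-class].
#' @slot psfFwhm PSF full width at half maximum in mm (0 disables blurring).
#' @slot D sparse down-sampling matrix (reconGrid -> grid), or NULL when the
#'   grids coincide.
#' @slot blur list of per-axis dense band matrices implementing the
#'   separable Gaussian, or empty when psfFwhm is 0.
#' @slot multFactors multiplicative correction [Sinogram-class], or NULL.
#' @slot components character description of the operator composition.
#'
#' @export
setClass("SystemModel",
  representation(grid = "ImageGrid", reconGrid = "ImageGrid",
                 geometry = "SinogramGeometry", psfFwhm = "numeric",
                 D = "ANY", blur = "list", multFactors = "ANY",
                 components = "character"))

#' Neighborhood: integer voxel offsets around a centre voxel
#'
#' The offsets of a (2r+1)^ndim box with the centre excluded, together with
#' their physical lengths in mm for the grid they were built on. When
#' neighbourhoods are compared across voxel sizes the physical extent in mm
#' is held fixed, so the same regularization hyperparameter can be reused.
#'
#' @slot offsets integer matrix, one row per neighbour offset.
#' @slot distances physical offset length in mm per row.
#' @slot voxelSize the mm voxel sizes the distances were computed with.
#'
#' @export
setClass("Neighborhood",
  representation(offsets = "matrix", distances = "numeric",
                 voxelSize = "numeric"))

setValidity("Neighborhood", function(object) {
  if (nrow(object@offsets) < 1L) return("neighborhood must be non-empty")
  if (any(rowSums(abs(object@offsets)) == 0))
    return("the zero (centre) offset must be excluded")
  if (anyDuplicated(split(object@offsets, row(object@offsets))))
    return("offsets must be unique")
  if (length(object@distances) != nrow(object@offsets))
    return("one distance per offset row required")
  if (any(object@distances <= 0)) return("distances must be positive")
  TRUE
})

#' PriorModel: smoothed Lange penalty with Bowsher similarity weights
#'
#' Holds the neighbourhood structure, raw inverse-distance proximity
#' weights (normalized per voxel over the in-bounds neighbourhood at
#' evaluation time, so the per-voxel sum is exactly 1 including at image
#' boundaries), the binary Bowsher similarity weights, and the two
#' hyperparameters: delta (edge preservation scale of the Lange potential,
#' image-intensity units) and beta (regularization strength).
#'
#' @slot neighborhood a [Neighborhood-class].
#' @slot xiRaw raw (un-normalized) proximity weight per offset, prop. 1/mm.
#' @slot w integer matrix (nvoxel x noffset) of binary similarity weights;
#'   entries for out-of-bounds neighbours are 0.
#' @slot delta Lange edge-preservation hyperparameter, > 0.
#' @slot beta regularization hyperparameter, >= 0.
#' @slot gridShape shape of the grid the prior was built for.
#'
#' @export
setClass("PriorModel",
  representation(neighborhood = "Neighborhood", xiRaw = "numeric",
                 w = "matrix", delta = "numeric", beta = "numeric",
                 gridShape = "integer"))

setValidity("PriorModel", function(object) {
  if (object@delta <= 0) return("delta must be > 0")
  if (object@beta < 0) return("beta must be >= 0")
  if (ncol(object@w) != nrow(object@neighborhood@offsets))
    return("w must have one column per neighbourhood offset")
  if (nrow(object@w) != prod(object@gridShape))
    return("w must have one row per voxel")
  if (!all(object@w %in% c(0L, 1L))) return("w entries must be binary")
  TRUE
})

#' CorrectionSet: multiplicative and additive correction sinograms
#'
#' @slot multiplicative attenuation x normalization factors (non-negative).
#' @slot additive expected randoms + scatter sinogram (non-negative).
#'
#' @export
setClass("CorrectionSet",
  representation(multiplicative = "Sinogram", additive = "Sinogram"))

setValidity("CorrectionSet", function(object) {
  dm <- dim(object@multiplicative@values); da <- dim(object@additive@values)
  if (!identical(dm, da)) return("multiplicative and additive shapes must match")
  if (any(object@multiplicative@values < 0) || any(object@additive@values < 0))
    return("corrections must be non-negative")
  TRUE
})

#' ReconstructionTrace: saved iterates and objective values
#'
#' @slot iterates list of [VolumeImage-class] saved on `schedule`.
#' @slot schedule integer iteration numbers of the saved iterates.
#' @slot logLik Poisson log-likelihood per saved iterate.
#' @slot objective logLik - beta * U per saved iterate (equals logLik when
#'   no prior is used).
#' @slot flags list of diagnostics (negativity-guard activations per
#'   iteration, frozen-voxel count).
#' @slot final the last iterate as a [VolumeImage-class].
#'
#' @export
setClass("ReconstructionTrace",
  representation(iterates = "list", schedule = "integer", logLik = "numeric",
                 objective = "numeric", flags = "list", final = "VolumeImage"))

#' PhantomStudy: ground truth plus one simulated noise realization
#'
#' @slot seed integer seed of the realization.
#' @slot prompts measured (noisy) prompts [Sinogram-class].
#' @slot trues,randoms,scatter the noisy components of the prompts.
#' @slot corrections the [CorrectionSet-class] (known means, idealized).
#' @slot groundTruth noise-free uptake [VolumeImage-class].
#' @slot roiMasks named list of logical arrays on the phantom grid.
#'
#' @export
setClass("PhantomStudy",
  representation(seed = "integer", prompts = "Sinogram", trues = "Sinogram",
                 randoms = "Sinogram", scatter = "Sinogram",
                 corrections = "CorrectionSet", groundTruth = "VolumeImage",
                 roiMasks = "list"))
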