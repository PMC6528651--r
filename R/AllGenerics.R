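#' Forward-project an image through a system model
#'
#' Applies the full forward operator of a [SystemModel-class]:
#' PSF blur (if any), down-sampling D (if any), Siddon ray tracing, and the
#' multiplicative correction factors (if any). Linear; accepts images with
#' negative values (e.g. gradients).
#'
#' @param model a [SystemModel-class].
#' @param image a [VolumeImage-class] on the model's reconstruction grid.
#' @return a [Sinogram-class] with role "generic".
#' @export
setGeneric("forwardProject", function(model, image) standardGeneric("forwardProject"))

#' Back-project a sinogram through a system model
#'
#' Applies the exact adjoint of [forwardProject()]: multiplicative factors,
#' Siddon adjoint, D transpose (if any), PSF blur (self-adjoint).
#'
#' @param model a [SystemModel-class].
#' @param sino a [Sinogram-class] on the model's geometry.
#' @return a [VolumeImage-class] on the model's reconstruction grid.
#' @export
setGeneric("backProject", function(model, sino) standardGeneric("backProject"))

#' @rdname imageGrid
#' @param x object to extract the grid from.
#' @export
setGeneric("grid2D", function(x) standardGeneric("grid2D"))

#' Extract the numeric values array
#' @param x a VolumeImage or Sinogram.
#' @return the underlying numeric array.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Replace the numeric values array
#' @param x a VolumeImage or Sinogram.
#' @param value replacement array of identical dimensions.
#' @export
setGeneric("values<-", function(x, value) standardGeneric("values<-"))
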