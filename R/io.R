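## Volume I/O through NIfTI-1 (voxel sizes carried in the header; the array
## axis order is x, y[, z] and the grid is centred on the scanner axis) and
## a documented plain-text JSON container for sinograms.

#' Write a volume image as NIfTI-1
#'
#' @param image a [VolumeImage-class].
#' @param path output path (".nii" or ".nii.gz").
#' @return the path, invisibly.
#' @export
writeVolume <- function(image, path) {
  nif <- RNifti::asNifti(image@values)
  RNifti::pixdim(nif) <- image@grid@voxelSize
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a VolumeImage
#'
#' Voxel sizes are taken from the header; the grid origin is centred on the
#' scanner axis (the package's geometry convention — NIfTI orientation
#' matrices are not interpreted).
#'
#' @param path NIfTI file path.
#' @return a [VolumeImage-class].
#' @export
readVolume <- function(path) {
  nif <- RNifti::readNifti(path)
  arr <- array(as.numeric(nif), dim = dim(nif))
  vox <- RNifti::pixdim(nif)[seq_along(dim(arr))]
  volumeImage(arr, imageGrid(dim(arr), vox))
}

#' Write a sinogram to the JSON container
#'
#' Plain-text container with named fields: `values` (column-major flat
#' array), `dim`, `radialBinSize` (mm), `nAngles`, `nPlanes`, `role`.
#'
#' @param sino a [Sinogram-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSinogram <- function(sino, path) {
  g <- sino@geometry
  jsonlite::write_json(
    list(values = as.numeric(sino@values), dim = dim(sino@values),
         nRadial = g@nRadial, radialBinSize = g@radialBinSize,
         nAngles = g@nAngles, nPlanes = g@nPlanes, role = sino@role),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sinogram from the JSON container
#'
#' @param path path written by [writeSinogram()].
#' @return a [Sinogram-class].
#' @export
readSinogram <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- sinogramGeometry(x$nRadial, x$nAngles, x$radialBinSize, x$nPlanes)
  sinogram(array(x$values, dim = unlist(x$dim)), geom, x$role)
}
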