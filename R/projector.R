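## Siddon projector, interpolation operators, PSF blurring and the composed
## high-resolution system matrix P_hr = X_lr D (with exact transpose
## P_hr' = D' X_lr'), so that the projector/backprojector pair is matched.

.ndimGrid <- function(grid) length(grid@shape)

.checkDims <- function(grid, geometry) {
  nd <- .ndimGrid(grid)
  if (nd == 2L && geometry@nPlanes != 1L)
    stop("2-D image with multi-plane sinogram geometry")
  if (nd == 3L && geometry@nPlanes != grid@shape[3])
    stop("3-D image planes must equal sinogram nPlanes (slice-stacked geometry)")
  invisible(TRUE)
}

#' Siddon forward projection
#'
#' Ray-traces the image along every line of response of the parallel-beam
#' geometry; each sinogram bin is the intersection-length-weighted sum (in
#' mm) of the voxel values along its ray. Rays missing the field of view are
#' exactly zero. For 3-D inputs the axial planes are projected
#' independently (slice-stacked geometry).
#'
#' @param image a [VolumeImage-class] (may contain negative values).
#' @param geometry a [SinogramGeometry-class].
#' @return a [Sinogram-class] of role "generic".
#' @seealso [siddonBackward()], [buildSystemModel()]
#' @export
siddonForward <- function(image, geometry) {
  grid <- image@grid
  .checkDims(grid, geometry)
  v <- cpp_siddon(as.numeric(image@values), grid@shape[1:2],
                  grid@voxelSize[1:2], grid@origin[1:2],
                  radialOffsets(geometry), projectionAngles(geometry),
                  geometry@nPlanes, TRUE)
  sinogram(v, geometry)
}

#' Siddon back projection (exact adjoint of the forward projection)
#'
#' @param sino a [Sinogram-class].
#' @param grid the target [ImageGrid-class].
#' @return a [VolumeImage-class].
#' @export
siddonBackward <- function(sino, grid) {
  .checkDims(grid, sino@geometry)
  v <- cpp_siddon(as.numeric(sino@values), grid@shape[1:2],
                  grid@voxelSize[1:2], grid@origin[1:2],
                  radialOffsets(sino@geometry), projectionAngles(sino@geometry),
                  sino@geometry@nPlanes, FALSE)
  volumeImage(array(v, dim = grid@shape), grid)
}

## Sparse matrix sampling a source-grid image at the voxel centres of a
## destination grid with bi/trilinear weights (coordinates clamped to the
## source-centre hull). Rows sum to 1: it is the standard interpolation
## dst <- src. Its transpose (column weights, computed from the destination
## voxel coordinates) is the raw down/up-sampling weight matrix.
.sampleMatrix <- function(srcGrid, dstGrid) {
  nd <- .ndimGrid(srcGrid)
  axw <- vector("list", nd)
  for (ax in seq_len(nd)) {
    f <- (voxelCenters(dstGrid, ax) - srcGrid@origin[ax]) / srcGrid@voxelSize[ax]
    n <- srcGrid@shape[ax]
    if (n == 1L) {
      i0 <- rep(1L, length(f)); fr <- rep(0, length(f))
    } else {
      i0 <- floor(f)
      fr <- f - i0
      low <- i0 < 0; high <- i0 > n - 2
      i0[low] <- 0; fr[low] <- 0
      i0[high] <- n - 2; fr[high] <- 1
      i0 <- as.integer(i0) + 1L
    }
    axw[[ax]] <- list(i0 = i0, fr = fr, n = n)
  }
  ndst <- prod(dstGrid@shape)
  nsrc <- prod(srcGrid@shape)
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  ii <- jj <- ww <- vector("list", nrow(corners))
  dstIdx <- arrayInd(seq_len(ndst), dstGrid@shape)
  for (c in seq_len(nrow(corners))) {
    srcSub <- matrix(0L, ndst, nd)
    wt <- rep(1, ndst)
    for (ax in seq_len(nd)) {
      a <- axw[[ax]]
      k <- dstIdx[, ax]
      srcSub[, ax] <- a$i0[k] + corners[c, ax]
      wt <- wt * if (corners[c, ax] == 1L) a$fr[k] else (1 - a$fr[k])
    }
    lin <- srcSub[, 1]
    mul <- 1L
    for (ax in 2:nd) {
      mul <- mul * srcGrid@shape[ax - 1]
      lin <- lin + (srcSub[, ax] - 1L) * mul
    }
    keep <- wt > 0
    ii[[c]] <- which(keep); jj[[c]] <- lin[keep]; ww[[c]] <- wt[keep]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                       dims = c(ndst, nsrc))
}

.sameFov <- function(hrGrid, lrGrid) {
  all(abs(fovExtent(hrGrid) - fovExtent(lrGrid)) <= lrGrid@voxelSize + 1e-9)
}

#' Build the trilinear down-sampling operator D (high -> low resolution)
#'
#' Assembles the sparse interpolation matrix that maps a high-resolution
#' image to a coarser grid. The bi/trilinear weights are computed from the
#' high-resolution voxel coordinates, so each high-resolution voxel is tied
#' to its 4 (2-D) or 8 (3-D) nearest low-resolution neighbours — the same
#' coupling in both the down-sampling and its transpose (the up-sampling
#' used in the adjoint). Rows are then normalized so that a constant image
#' maps to the same constant; the transpose is used as-is, without
#' renormalization, so that the pair is an exact matrix transpose.
#'
#' @param hrGrid source (finer) [ImageGrid-class].
#' @param lrGrid destination (coarser) [ImageGrid-class]; must cover the
#'   same physical FOV within one low-resolution voxel.
#' @return a sparse dgCMatrix of dimension prod(lr shape) x prod(hr shape).
#' @export
downsampleMatrix <- function(hrGrid, lrGrid) {
  if (.ndimGrid(hrGrid) != .ndimGrid(lrGrid)) stop("grid dimensionality mismatch")
  if (any(lrGrid@voxelSize < hrGrid@voxelSize - 1e-9))
    stop("lrGrid voxels must not be smaller than hrGrid voxels (wrong direction)")
  if (!.sameFov(hrGrid, lrGrid))
    stop("hrGrid and lrGrid must cover the same physical FOV (within one lr voxel)")
  Draw <- Matrix::t(.sampleMatrix(lrGrid, hrGrid))  # columns: hr voxel weights
  rs <- Matrix::rowSums(Draw)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% Draw
}

#' Down-sample an image to a coarser grid (the operator D)
#'
#' @param hr high-resolution [VolumeImage-class].
#' @param lrGrid coarser target [ImageGrid-class].
#' @return a [VolumeImage-class] on `lrGrid`.
#' @export
downsampleImage <- function(hr, lrGrid) {
  D <- downsampleMatrix(hr@grid, lrGrid)
  volumeImage(array(as.numeric(D %*% as.numeric(hr@values)),
                    dim = lrGrid@shape), lrGrid)
}

#' Up-sample by the exact transpose of the down-sampling operator
#'
#' Applies D' with exactly the weights of [downsampleImage()], transposed.
#' This is NOT a generic interpolation: it is the adjoint required for a
#' matched projector/backprojector pair (use [interpolateToGrid()] for
#' ordinary image resampling).
#'
#' @param lr low-resolution [VolumeImage-class].
#' @param hrGrid finer target [ImageGrid-class].
#' @return a [VolumeImage-class] on `hrGrid`.
#' @export
upsampleTranspose <- function(lr, hrGrid) {
  D <- downsampleMatrix(hrGrid, lr@grid)
  volumeImage(array(as.numeric(Matrix::crossprod(D, as.numeric(lr@values))),
                    dim = hrGrid@shape), hrGrid)
}

#' Resample an image onto another grid with bi/trilinear interpolation
#'
#' Ordinary interpolation (rows sum to one); used e.g. to bring
#' standard-resolution reconstructions onto the high-resolution metric grid.
#'
#' @param image a [VolumeImage-class].
#' @param grid target [ImageGrid-class].
#' @return a [VolumeImage-class] on `grid`.
#' @export
interpolateToGrid <- function(image, grid) {
  if (identical(image@grid@shape, grid@shape) &&
      all(abs(image@grid@voxelSize - grid@voxelSize) < 1e-12) &&
      all(abs(image@grid@origin - grid@origin) < 1e-12)) return(image)
  M <- .sampleMatrix(image@grid, grid)
  volumeImage(array(as.numeric(M %*% as.numeric(image@values)),
                    dim = grid@shape), grid)
}

## ---- PSF blurring ----

.gaussBand <- function(n, fwhmMm, voxMm) {
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / voxMm
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  B <- matrix(0, n, n)
  for (k in seq_along(x)) {
    d <- x[k]
    idx <- seq_len(n - abs(d))
    if (d >= 0) B[cbind(idx + d, idx)] <- g[k] else B[cbind(idx, idx - d)] <- g[k]
  }
  B
}

.blurOperators <- function(grid, fwhmMm) {
  if (fwhmMm <= 0) return(list())
  lapply(seq_len(.ndimGrid(grid)), function(ax)
    .gaussBand(grid@shape[ax], fwhmMm, grid@voxelSize[ax]))
}

.applyBlur <- function(blur, v) {
  if (length(blur) == 0L) return(v)
  d <- dim(v)
  if (length(d) == 2L) {
    out <- blur[[1]] %*% v %*% blur[[2]]  # band matrices are symmetric
    return(array(as.numeric(out), dim = d))
  }
  out <- v
  for (k in seq_len(d[3]))
    out[, , k] <- as.numeric(blur[[1]] %*% out[, , k] %*% blur[[2]])
  m <- matrix(out, nrow = d[1] * d[2], ncol = d[3])
  array(as.numeric(m %*% blur[[3]]), dim = d)
}

#' Image-space Gaussian PSF blurring
#'
#' Convolution with an isotropic Gaussian of the stated full width at half
#' maximum in mm (converted to voxels through the grid spacing), separable
#' per axis, kernel truncated at 4 sigma and normalized to unit sum.
#' Zero-padding boundaries without kernel renormalization are used so that
#' the operator is exactly self-adjoint, as required for a matched system
#' model; total intensity is preserved for images supported away from the
#' boundary.
#'
#' @param image a [VolumeImage-class].
#' @param fwhmMm FWHM in mm; 0 returns the input unchanged.
#' @return a [VolumeImage-class].
#' @export
psfBlur <- function(image, fwhmMm) {
  if (fwhmMm < 0) stop("fwhmMm must be >= 0")
  if (fwhmMm == 0) return(image)
  blur <- .blurOperators(image@grid, fwhmMm)
  volumeImage(.applyBlur(blur, image@values), image@grid)
}

## ---- system model ----

#' Build a (possibly high-resolution) PET system model
#'
#' Composes the forward operator mult * X_lr(D(blur(theta))): an optional
#' image-space Gaussian PSF on the reconstruction grid, the trilinear
#' down-sampling D from the reconstruction grid to the projection grid
#' (identity when the grids coincide), the Siddon projector on the
#' projection grid, and optional multiplicative correction factors.
#' Reconstructing on a grid finer than the line-of-response sampling with a
#' plain ray-tracing projector leaves unsampled voxels and stripe/gap
#' artifacts; interposing D couples every fine voxel to the rays, which is
#' the high-resolution ("MRvox") mode.
#'
#' @param grid projection-side [ImageGrid-class] (the standard grid whose
#'   voxel size matches the radial sampling).
#' @param geometry a [SinogramGeometry-class].
#' @param psfFwhmMm PSF FWHM in mm (0 disables resolution modelling).
#' @param reconGrid grid to reconstruct on; defaults to `grid`. Must be at
#'   least as fine as `grid` and cover the same FOV.
#' @param multFactors multiplicative correction [Sinogram-class]
#'   (attenuation x normalization), or NULL.
#' @return a [SystemModel-class].
#' @export
buildSystemModel <- function(grid, geometry, psfFwhmMm = 0,
                             reconGrid = grid, multFactors = NULL) {
  .checkDims(grid, geometry)
  same <- identical(reconGrid@shape, grid@shape) &&
    all(abs(reconGrid@voxelSize - grid@voxelSize) < 1e-12) &&
    all(abs(reconGrid@origin - grid@origin) < 1e-12)
  if (!same && any(reconGrid@voxelSize > grid@voxelSize + 1e-9))
    stop("reconGrid must not be coarser than the projection grid")
  D <- if (same) NULL else downsampleMatrix(reconGrid, grid)
  if (!is.null(multFactors)) {
    if (!identical(dim(multFactors@values),
                   dim(sinogram(0, geometry)@values)))
      stop("multFactors dimensions do not match the sinogram geometry")
  }
  comps <- c(if (!is.null(multFactors)) "mult-factors",
             "siddon",
             if (!same) "downsample-D",
             if (psfFwhmMm > 0) sprintf("psf-%gmm", psfFwhmMm))
  new("SystemModel", grid = grid, reconGrid = reconGrid, geometry = geometry,
      psfFwhm = as.numeric(psfFwhmMm), D = D,
      blur = .blurOperators(reconGrid, psfFwhmMm),
      multFactors = multFactors, components = comps)
}

#' @rdname forwardProject
#' @export
setMethod("forwardProject", signature("SystemModel", "VolumeImage"),
  function(model, image) {
    if (!identical(dim(image@values), as.integer(model@reconGrid@shape)))
      stop("image is not on the model's reconstruction grid")
    v <- .applyBlur(model@blur, image@values)
    if (!is.null(model@D))
      v <- array(as.numeric(model@D %*% as.numeric(v)), dim = model@grid@shape)
    s <- cpp_siddon(as.numeric(v), model@grid@shape[1:2],
                    model@grid@voxelSize[1:2], model@grid@origin[1:2],
                    radialOffsets(model@geometry),
                    projectionAngles(model@geometry),
                    model@geometry@nPlanes, TRUE)
    out <- sinogram(s, model@geometry)
    if (!is.null(model@multFactors))
      out@values <- out@values * model@multFactors@values
    out
  })

#' @rdname backProject
#' @export
setMethod("backProject", signature("SystemModel", "Sinogram"),
  function(model, sino) {
    y <- sino@values
    if (!is.null(model@multFactors)) y <- y * model@multFactors@values
    v <- cpp_siddon(as.numeric(y), model@grid@shape[1:2],
                    model@grid@voxelSize[1:2], model@grid@origin[1:2],
                    radialOffsets(model@geometry),
                    projectionAngles(model@geometry),
                    model@geometry@nPlanes, FALSE)
    v <- array(v, dim = model@grid@shape)
    if (!is.null(model@D))
      v <- array(as.numeric(Matrix::crossprod(model@D, as.numeric(v))),
                 dim = model@reconGrid@shape)
    volumeImage(.applyBlur(model@blur, v), model@reconGrid)
  })

#' Singular values of the system matrix restricted to a central patch
#'
#' Assembles the dense system matrix column by column (one forward
#' projection per patch voxel) for the voxels of the reconstruction grid
#' inside a box of the given physical extent centred on the scanner axis,
#' and returns its singular values sorted in descending order. Used to
#' compare the frequency recovery of the standard and the high-resolution
#' (down-sampling-composed) system matrices.
#'
#' @param model a [SystemModel-class].
#' @param patchExtentMm physical box extent in mm, scalar or per axis.
#' @param maxColumns safety limit on the dense assembly (default 4096).
#' @return numeric vector of singular values, descending.
#' @export
patchSingularValues <- function(model, patchExtentMm, maxColumns = 4096L) {
  g <- model@reconGrid
  nd <- .ndimGrid(g)
  ext <- rep_len(patchExtentMm, nd)
  inPatch <- lapply(seq_len(nd), function(ax)
    abs(voxelCenters(g, ax)) <= ext[ax] / 2 + 1e-9)
  ai <- arrayInd(seq_len(prod(g@shape)), g@shape)
  sel <- rep(TRUE, nrow(ai))
  for (ax in seq_len(nd)) sel <- sel & inPatch[[ax]][ai[, ax]]
  idx <- which(sel)
  if (length(idx) == 0L) stop("patch contains no voxels")
  if (length(idx) > maxColumns)
    stop("patch too large for dense assembly (", length(idx), " columns)")
  nbin <- length(sinogram(0, model@geometry)@values)
  A <- matrix(0, nbin, length(idx))
  e <- volumeImage(0, g)
  for (c in seq_along(idx)) {
    v <- e@values; v[idx[c]] <- 1; e@values <- v
    A[, c] <- as.numeric(forwardProject(model, e)@values)
    v[idx[c]] <- 0; e@values <- v
  }
  sort(svd(A, nu = 0, nv = 0)$d, decreasing = TRUE)
}
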