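## Smoothed Lange prior with normalized inverse-distance proximity weights
## and modified (asymmetric) Bowsher anatomical similarity weights, plus the
## delta-dependent beta scaling rule used for hyperparameter selection.

#' Lange (Fair) potential function
#'
#' psi(t) = delta * ( |t|/delta - log(1 + |t|/delta) ). Even, zero at 0,
#' monotone in |t|; approximately t^2/(2 delta) for |t| << delta (quadratic
#' regime) and approximately |t| - delta log(|t|/delta) for |t| >> delta
#' (TV-like regime). `delta` has image-intensity units and controls the
#' level of edge preservation.
#'
#' @param t numeric vector of intensity differences.
#' @param delta edge-preservation hyperparameter, > 0.
#' @return non-negative numeric vector.
#' @examples
#' langePotential(1, delta = 1)  # 1 - log(2)
#' @export
langePotential <- function(t, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive scalar")
  a <- abs(t) / delta
  delta * (a - log1p(a))
}

#' Box neighbourhood of integer voxel offsets
#'
#' All offsets of a boxSize^ndim box centred on (and excluding) the centre
#' voxel, in lexicographic offset order (the deterministic tie-break order
#' used by the Bowsher selection).
#'
#' @param boxSize odd box edge in voxels, scalar or per axis (e.g. 5 for the
#'   5x5(x5) neighbourhood).
#' @param voxelSize mm per axis; used for the physical offset distances.
#' @param ndim 2 or 3.
#' @return a [Neighborhood-class].
#' @export
boxNeighborhood <- function(boxSize, voxelSize, ndim = length(voxelSize)) {
  boxSize <- as.integer(rep_len(boxSize, ndim))
  if (any(boxSize < 1L) || any(boxSize %% 2L == 0L))
    stop("boxSize entries must be odd and >= 1")
  voxelSize <- rep_len(as.numeric(voxelSize), ndim)
  half <- (boxSize - 1L) %/% 2L
  off <- as.matrix(expand.grid(lapply(seq_len(ndim),
                                      function(ax) (-half[ax]):half[ax])))
  # lexicographic order over (o1, o2[, o3])
  off <- off[do.call(order, as.data.frame(off)), , drop = FALSE]
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  dimnames(off) <- NULL
  storage.mode(off) <- "integer"
  d <- sqrt(colSums((t(off) * voxelSize)^2))
  new("Neighborhood", offsets = off, distances = d, voxelSize = voxelSize)
}

#' Neighbourhood of fixed physical extent
#'
#' When grids of different voxel size are compared, the neighbourhood's
#' physical size in mm is held fixed so the same regularization strength
#' applies: the box edge in voxels is the odd integer nearest to
#' extentMm / voxelSize (at least 3).
#'
#' @param extentMm physical box edge in mm (e.g. 5 for a 5 mm patch).
#' @param voxelSize mm per axis.
#' @param ndim 2 or 3.
#' @return a [Neighborhood-class].
#' @export
neighborhoodFromExtent <- function(extentMm, voxelSize, ndim = length(voxelSize)) {
  voxelSize <- rep_len(as.numeric(voxelSize), ndim)
  n <- extentMm / voxelSize
  odd <- pmax(3L, 2L * as.integer(round((n - 1) / 2)) + 1L)
  boxNeighborhood(odd, voxelSize, ndim)
}

#' Normalized inverse-distance proximity weights
#'
#' xi_jk proportional to 1 / (physical distance between voxels j and k),
#' normalized to sum to 1 over the neighbourhood. At image boundaries the
#' prior renormalizes over the truncated (in-bounds) neighbourhood at
#' evaluation time, so the per-voxel sum is 1 everywhere.
#'
#' @param neigh a [Neighborhood-class].
#' @return numeric vector of normalized weights, one per offset.
#' @export
proximityWeights <- function(neigh) {
  xi <- 1 / neigh@distances
  xi / sum(xi)
}

#' Modified (asymmetric) Bowsher similarity weights
#'
#' For every voxel, the B neighbours most similar in the anatomical image
#' (smallest absolute intensity difference) receive weight 1, the rest 0.
#' The selection is asymmetric: w_jk need not equal w_kj. Ties are broken
#' deterministically by smaller physical distance, then by lexicographic
#' offset order. At boundary voxels all min(B, available) in-bounds
#' neighbours are selected.
#'
#' @param anatomical the guidance [VolumeImage-class] (e.g. a T1-weighted
#'   MR image resampled to the reconstruction grid).
#' @param neigh a [Neighborhood-class].
#' @param B number of neighbours to select (<= neighbourhood size).
#' @return integer matrix (nvoxel x noffset) of binary weights.
#' @export
bowsherWeights <- function(anatomical, neigh, B) {
  K <- nrow(neigh@offsets)
  if (B < 1L || B > K) stop("B must be between 1 and the neighbourhood size")
  cpp_bowsher(as.numeric(anatomical@values), dim(anatomical@values),
              neigh@offsets, neigh@distances, as.integer(B))
}

#' Construct a smoothed-Lange prior model
#'
#' @param grid the reconstruction [ImageGrid-class].
#' @param neigh a [Neighborhood-class]; defaults to the box of 5 mm physical
#'   extent on this grid (5x5(x5) voxels at 1 mm spacing).
#' @param anatomical optional guidance [VolumeImage-class] on `grid`; when
#'   given, Bowsher similarity weights are computed, otherwise all
#'   neighbours are kept (non-guided MAP).
#' @param B Bowsher neighbour count; default one third of the neighbourhood
#'   size (rounded), matching the 40-of-124 proportion used with the
#'   5x5x5 neighbourhood.
#' @param delta Lange edge-preservation hyperparameter (> 0, image units).
#' @param beta regularization hyperparameter (>= 0).
#' @return a [PriorModel-class].
#' @export
priorModel <- function(grid, neigh = NULL, anatomical = NULL, B = NULL,
                       delta, beta) {
  if (is.null(neigh))
    neigh <- neighborhoodFromExtent(5, grid@voxelSize)
  K <- nrow(neigh@offsets)
  if (!is.null(anatomical)) {
    if (!identical(dim(anatomical@values), as.integer(grid@shape)))
      stop("anatomical image must be on the reconstruction grid")
    if (is.null(B)) B <- max(1L, as.integer(round(K / 3.1)))
    w <- bowsherWeights(anatomical, neigh, B)
  } else {
    w <- matrix(1L, prod(grid@shape), K)
  }
  new("PriorModel", neighborhood = neigh, xiRaw = 1 / neigh@distances,
      w = w, delta = as.numeric(delta), beta = as.numeric(beta),
      gridShape = as.integer(grid@shape))
}

.checkPriorImage <- function(theta, prior) {
  if (!identical(dim(theta@values), prior@gridShape))
    stop("image shape does not match the grid the prior was built for")
}

#' Smoothed Lange energy
#'
#' U(theta) = sum_j psi( sqrt( sum_k xi_jk w_jk (theta_j - theta_k)^2 ) ):
#' the Lange potential of each voxel's weighted root-mean-square difference
#' to its neighbours. Zero for constant images.
#'
#' @param theta a [VolumeImage-class].
#' @param prior a [PriorModel-class] built on theta's grid.
#' @return non-negative scalar.
#' @export
smoothedLangeEnergy <- function(theta, prior) {
  .checkPriorImage(theta, prior)
  cpp_smoothed_lange(as.numeric(theta@values), prior@gridShape,
                     prior@neighborhood@offsets, prior@xiRaw, prior@w,
                     prior@delta, 0L)$energy
}

#' Smoothed Lange penalty derivative
#'
#' The one-sided form (default) is the printed derivative used in the
#' one-step-late update:
#' dU/dtheta_j = sum_k xi_jk w_jk (theta_j - theta_k) / (delta + t_j) with
#' t_j the local weighted RMS difference. With `symmetrized = TRUE` the
#' neighbour terms' dependence on theta_j is included, giving the exact
#' gradient of [smoothedLangeEnergy()] (useful for numeric gradient checks).
#'
#' @param theta a [VolumeImage-class].
#' @param prior a [PriorModel-class] built on theta's grid.
#' @param symmetrized use the full derivative of the energy.
#' @return a [VolumeImage-class] holding the per-voxel derivative.
#' @export
smoothedLangeGradient <- function(theta, prior, symmetrized = FALSE) {
  .checkPriorImage(theta, prior)
  res <- cpp_smoothed_lange(as.numeric(theta@values), prior@gridShape,
                            prior@neighborhood@offsets, prior@xiRaw, prior@w,
                            prior@delta, if (symmetrized) 1L else 0L)
  volumeImage(array(res$grad, dim = prior@gridShape), theta@grid)
}

#' Scale beta with delta for matched regularization strength
#'
#' The Lange potential's scale depends on delta, so changing delta at fixed
#' beta changes the effective regularization. The reference pair
#' (delta0, beta0) is translated to any delta by
#' beta = k(delta) * beta0, k(delta) = (Dtheta + delta0) / (Dtheta + delta),
#' where Dtheta is the range of intensity differences to be penalized,
#' taken as a fraction (default 25%) of the image dynamic range. k(delta0)
#' is exactly 1 and k decreases monotonically in delta.
#'
#' @param delta the delta value to use.
#' @param delta0 reference delta (conventionally 0.1 * Dtheta).
#' @param beta0 reference beta.
#' @param imageDynamicRange max - min of the image estimate (from a pilot
#'   MLEM reconstruction; see [deltaRule()]).
#' @param dynamicRangeFraction fraction of the dynamic range defining
#'   Dtheta (default 0.25).
#' @return the scaled beta.
#' @export
scaleBeta <- function(delta, delta0, beta0, imageDynamicRange,
                      dynamicRangeFraction = 0.25) {
  dtheta <- dynamicRangeFraction * imageDynamicRange
  if (!is.finite(dtheta) || dtheta <= 0)
    stop("dynamic range must be positive")
  beta0 * (dtheta + delta0) / (dtheta + delta)
}

#' Derive (Dtheta, delta0) from a pilot image
#'
#' Dtheta is a fraction (default 25%) of the pilot image's dynamic range
#' (max - min), and delta0 = 0.1 * Dtheta, putting the reference potential
#' in its TV-like regime. The pilot is conventionally a short (e.g.
#' 20-iteration) MLEM reconstruction, which is reproducible and avoids the
#' degenerate dynamic range of a uniform initialization.
#'
#' @param pilot a [VolumeImage-class].
#' @param dynamicRangeFraction fraction defining Dtheta (default 0.25).
#' @param delta0Fraction delta0 as a fraction of Dtheta (default 0.1).
#' @return list with elements dynamicRange, dtheta, delta0.
#' @export
deltaRule <- function(pilot, dynamicRangeFraction = 0.25,
                      delta0Fraction = 0.1) {
  dr <- max(pilot@values) - min(pilot@values)
  dtheta <- dynamicRangeFraction * dr
  list(dynamicRange = dr, dtheta = dtheta, delta0 = delta0Fraction * dtheta)
}
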