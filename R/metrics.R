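## ROI evaluation metrics: contrast against white matter, regional
## coefficient of variation, ensemble NRMSE and ensemble COV. All metrics
## are computed on the high-resolution (anatomical) grid; coarser
## reconstructions are interpolated up first with interpolateToGrid().

.maskValues <- function(image, mask) {
  if (!identical(dim(mask), dim(image@values)))
    stop("mask dimensions do not match the image")
  image@values[mask]
}

#' ROI contrast against white matter
#'
#' Mean over the region of interest divided by the mean over the
#' white-matter reference region: C = mean_R(theta) / mean_W(theta).
#'
#' @param image a [VolumeImage-class].
#' @param roi logical mask of the region of interest.
#' @param wm logical mask of the white-matter reference.
#' @return positive scalar.
#' @export
roiContrast <- function(image, roi, wm) {
  if (!any(roi) || !any(wm)) stop("masks must be non-empty")
  den <- mean(.maskValues(image, wm))
  if (den == 0) stop("white-matter mean is zero")
  mean(.maskValues(image, roi)) / den
}

#' Regional coefficient of variation (noise metric)
#'
#' Sample standard deviation over the ROI (N - 1 denominator) divided by
#' the ROI mean. Scale invariant.
#'
#' @param image a [VolumeImage-class].
#' @param roi logical mask with at least 2 voxels.
#' @return non-negative scalar.
#' @export
roiCov <- function(image, roi) {
  v <- .maskValues(image, roi)
  if (length(v) < 2L) stop("roi must contain at least 2 voxels")
  m <- mean(v)
  if (m == 0) stop("roi mean is zero")
  stats::sd(v) / m
}

#' Ensemble NRMSE of an ROI mean (error metric over noise realizations)
#'
#' NRMSE_R = sqrt( (1/M) sum_m (mean_R(theta_m) - mean_R(truth))^2 /
#' mean_R(truth) ), with the squared deviation divided by the first power
#' of the truth mean (the printed definition, which makes the metric carry
#' the square root of intensity units). `normalization = "mean2"` divides
#' by the squared truth mean instead, giving the conventional dimensionless
#' relative error, for sensitivity analysis.
#'
#' @param images list of [VolumeImage-class] realizations (same grid).
#' @param truth ground-truth [VolumeImage-class].
#' @param roi logical mask.
#' @param normalization "mean" (printed form, default) or "mean2".
#' @return non-negative scalar.
#' @export
roiNrmse <- function(images, truth, roi, normalization = c("mean", "mean2")) {
  normalization <- match.arg(normalization)
  if (length(images) < 1L) stop("at least one realization required")
  tMean <- mean(.maskValues(truth, roi))
  if (tMean <= 0) stop("truth ROI mean must be positive")
  dev2 <- vapply(images,
                 function(im) (mean(.maskValues(im, roi)) - tMean)^2,
                 numeric(1))
  den <- if (normalization == "mean") tMean else tMean^2
  sqrt(mean(dev2 / den))
}

#' Mean ensemble COV over an ROI (noise metric over realizations)
#'
#' Per-voxel ensemble standard deviation across the M realizations (M - 1
#' denominator) divided by the per-voxel ensemble mean, averaged over the
#' ROI voxels. Voxels with zero ensemble mean are excluded with a warning
#' rather than propagating infinities.
#'
#' @param images list of at least two [VolumeImage-class] realizations.
#' @param roi logical mask.
#' @return non-negative scalar.
#' @export
ensembleCov <- function(images, roi) {
  if (length(images) < 2L) stop("at least two realizations required")
  V <- vapply(images, function(im) .maskValues(im, roi),
              numeric(sum(roi)))
  if (is.null(dim(V))) V <- matrix(V, nrow = 1L)  # single-voxel ROI
  mu <- rowMeans(V)
  sdv <- apply(V, 1, stats::sd)
  ok <- mu > 0
  if (!all(ok))
    warning(sum(!ok), " ROI voxel(s) with zero ensemble mean excluded")
  if (!any(ok)) stop("all ROI voxels have zero ensemble mean")
  mean(sdv[ok] / mu[ok])
}

#' Resample ROI masks onto a metric grid
#'
#' Transfers logical masks to another grid by interpolating the indicator
#' and keeping voxels with interpolated weight above one half (voxels
#' exactly on a region boundary belong to neither mask, keeping distinct
#' masks disjoint). Used when reconstructions and metrics live on the
#' high-resolution grid but the masks were defined on a different one.
#'
#' @param masks named list of logical arrays on `fromGrid`.
#' @param fromGrid source [ImageGrid-class].
#' @param toGrid target [ImageGrid-class].
#' @return named list of logical arrays on `toGrid`.
#' @export
resampleMasks <- function(masks, fromGrid, toGrid) {
  lapply(masks, function(m) {
    im <- interpolateToGrid(volumeImage(array(as.numeric(m), dim(m)), fromGrid),
                            toGrid)
    im@values > 0.5
  })
}

#' Compute all ROI metrics for one image on the metric grid
#'
#' Interpolates the image to the metric grid and evaluates [roiContrast()]
#' and [roiCov()] for every ROI against the white-matter reference.
#'
#' @param image a [VolumeImage-class].
#' @param metricGrid the (high-resolution) [ImageGrid-class] metrics are
#'   computed on.
#' @param roiMasks named list of logical masks on `metricGrid`; must
#'   contain a `whiteMatter` element (the reference) — the other entries
#'   are evaluated as ROIs.
#' @return data.frame with columns roi, contrast, cov.
#' @export
roiMetricTable <- function(image, metricGrid, roiMasks) {
  if (is.null(roiMasks$whiteMatter)) stop("roiMasks must contain whiteMatter")
  im <- interpolateToGrid(image, metricGrid)
  wm <- roiMasks$whiteMatter
  rois <- roiMasks[setdiff(names(roiMasks), "whiteMatter")]
  data.frame(
    roi = names(rois),
    contrast = vapply(rois, function(r) roiContrast(im, r, wm), numeric(1)),
    cov = vapply(rois, function(r) roiCov(im, r), numeric(1)),
    row.names = NULL)
}
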