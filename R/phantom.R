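## Procedural brain-like phantom and the emission-data simulator: labelled
## tissue classes, FDG-like uptake (gray matter 4x white matter),
## two-tissue attenuation map, pseudo-T1 anatomical image, system blurring,
## attenuation/normalization factors, randoms and scatter components, and
## seeded Poisson noise realizations.

.tissueLabels <- c(background = 0L, csf = 1L, gray = 2L, white = 3L,
                   bone = 4L, soft = 5L, caudate = 6L, putamen = 7L,
                   accumbens = 8L)

#' Default phantom specification
#'
#' A 2-D brain-like slice drawn with parametric shapes on a 1 mm grid:
#' an outer soft-tissue ellipse, a bone (skull) shell, a CSF layer, a
#' cortical gray-matter ribbon, the white-matter interior, two ventricles,
#' and three pairs of small striatum-like gray-matter structures (caudate,
#' putamen, nucleus accumbens). Later shapes overwrite earlier ones.
#' Uptake is FDG-like with gray matter exactly 4x white matter; the
#' attenuation map uses exactly two tissue values (soft tissue and bone);
#' the pseudo-T1 image assigns distinct per-tissue intensities (white
#' matter bright, gray matter intermediate, CSF dark) with mild smoothing
#' and optional intensity noise, standing in for an MR simulation (it only
#' needs to provide rank-order similarity structure aligned with the
#' labels).
#'
#' @param n grid extent in voxels (default 176, i.e. a 176 mm FOV at 1 mm).
#' @param voxelSize phantom voxel size in mm (default 1).
#' @param gmWmRatio gray/white uptake ratio (default 4).
#' @param uptake named uptake per tissue class (arbitrary units).
#' @param mu named attenuation per tissue in 1/mm: soft tissue 0.0096,
#'   bone 0.0151 (511 keV values).
#' @param t1Intensity named pseudo-T1 intensity per tissue.
#' @param t1NoiseSd relative Gaussian noise on the pseudo-T1 (default 0.01).
#' @return a list spec consumed by [makePhantom()].
#' @export
phantomSpec <- function(n = 176L, voxelSize = 1,
                        gmWmRatio = 4,
                        uptake = c(background = 0, csf = 0.1, gray = NA,
                                   white = 1, bone = 0, soft = 0.5,
                                   caudate = NA, putamen = NA, accumbens = NA),
                        mu = c(soft = 0.0096, bone = 0.0151),
                        t1Intensity = c(background = 0, csf = 0.18,
                                        gray = 0.55, white = 1, bone = 0.12,
                                        soft = 0.4, caudate = 0.55,
                                        putamen = 0.55, accumbens = 0.55),
                        t1NoiseSd = 0.01) {
  gm <- gmWmRatio * uptake[["white"]]
  for (nm in c("gray", "caudate", "putamen", "accumbens"))
    if (is.na(uptake[[nm]])) uptake[[nm]] <- gm
  list(grid = imageGrid(c(n, n), voxelSize), uptake = uptake, mu = mu,
       t1Intensity = t1Intensity, t1NoiseSd = t1NoiseSd)
}

.paintEllipse <- function(labels, xs, ys, cx, cy, a, b, value) {
  d <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, `+`)
  labels[d <= 1] <- value
  labels
}

#' Build the labelled phantom and its derived volumes
#'
#' @param spec a specification from [phantomSpec()].
#' @param t1Seed seed for the pseudo-T1 intensity noise (NULL for none).
#' @return list with [VolumeImage-class] elements `labels`, `uptake`,
#'   `muMap` (1/mm), `pseudoT1`, and `roiMasks`, a named list of logical
#'   arrays: corticalGM, corticalLeft, corticalRight, caudate, putamen,
#'   accumbens, grayAll (all gray-matter voxels) and whiteMatter (the
#'   reference region).
#' @export
makePhantom <- function(spec = phantomSpec(), t1Seed = 1L) {
  g <- spec$grid
  xs <- voxelCenters(g, 1); ys <- voxelCenters(g, 2)
  L <- .tissueLabels
  lab <- matrix(L[["background"]], g@shape[1], g@shape[2])
  # shapes in mm, centred on the scanner axis; later shapes overwrite
  lab <- .paintEllipse(lab, xs, ys, 0, 0, 80, 66, L[["soft"]])
  lab <- .paintEllipse(lab, xs, ys, 0, 0, 76, 62, L[["bone"]])
  lab <- .paintEllipse(lab, xs, ys, 0, 0, 71, 57, L[["csf"]])
  lab <- .paintEllipse(lab, xs, ys, 0, 0, 68, 54, L[["gray"]])
  lab <- .paintEllipse(lab, xs, ys, 0, 0, 61, 47, L[["white"]])
  lab <- .paintEllipse(lab, xs, ys, -11, 4, 13, 6, L[["csf"]])   # ventricles
  lab <- .paintEllipse(lab, xs, ys, 11, 4, 13, 6, L[["csf"]])
  for (s in c(-1, 1)) {                                          # striatum
    lab <- .paintEllipse(lab, xs, ys, s * 17, 18, 5, 5, L[["caudate"]])
    lab <- .paintEllipse(lab, xs, ys, s * 27, 0, 6.5, 6.5, L[["putamen"]])
    lab <- .paintEllipse(lab, xs, ys, s * 12, -18, 4, 4, L[["accumbens"]])
  }

  tissueOf <- names(L)[match(lab, L)]
  uptake <- array(as.numeric(spec$uptake[tissueOf]), dim = dim(lab))
  muMap <- array(0, dim = dim(lab))
  muMap[lab == L[["bone"]]] <- spec$mu[["bone"]]
  muMap[lab %in% setdiff(L, c(L[["background"]], L[["bone"]]))] <-
    spec$mu[["soft"]]

  t1 <- array(as.numeric(spec$t1Intensity[tissueOf]), dim = dim(lab))
  t1 <- .applyBlur(.blurOperators(g, 1), t1)  # 1 mm FWHM partial-volume blur
  if (!is.null(t1Seed) && spec$t1NoiseSd > 0) {
    set.seed(as.integer(t1Seed))
    t1 <- t1 + stats::rnorm(length(t1), 0, spec$t1NoiseSd * max(t1))
  }

  grayAll <- array(lab %in% c(L[["gray"]], L[["caudate"]], L[["putamen"]],
                              L[["accumbens"]]), dim = dim(lab))
  xIdx <- outer(xs, rep(1, length(ys)))
  rois <- list(
    corticalGM   = lab == L[["gray"]],
    corticalLeft = lab == L[["gray"]] & xIdx < 0,
    corticalRight = lab == L[["gray"]] & xIdx > 0,
    caudate      = lab == L[["caudate"]],
    putamen      = lab == L[["putamen"]],
    accumbens    = lab == L[["accumbens"]],
    grayAll      = grayAll,
    whiteMatter  = lab == L[["white"]])

  list(labels = volumeImage(array(as.numeric(lab), dim(lab)), g),
       uptake = volumeImage(uptake, g),
       muMap = volumeImage(muMap, g),
       pseudoT1 = volumeImage(t1, g),
       roiMasks = rois)
}

#' Simulate the noise-free emission data for a phantom
#'
#' The uptake volume is blurred with the system resolution kernel (default
#' 4.3 mm FWHM) and forward-projected with the Siddon projector on the
#' phantom grid. Attenuation factors are exp(-line integral of the
#' attenuation map along each ray); normalization factors follow a smooth
#' synthetic radial profile (default +/-10% cosine variation; set
#' `normAmplitude = 0` for unit normalization). The expected trues
#' sinogram is norm x attenuation x projection.
#'
#' @param phantom output of [makePhantom()].
#' @param geometry a [SinogramGeometry-class].
#' @param systemFwhmMm system resolution FWHM in mm (default 4.3).
#' @param normAmplitude amplitude of the radial normalization variation
#'   (default 0.1).
#' @return list with `truesMean` (Sinogram), `attenuation`,
#'   `normalization` (factor Sinograms) and `blurredUptake`.
#' @export
simulateNoiseFree <- function(phantom, geometry, systemFwhmMm = 4.3,
                              normAmplitude = 0.1) {
  blurred <- psfBlur(phantom$uptake, systemFwhmMm)
  proj <- siddonForward(blurred, geometry)
  att <- siddonForward(phantom$muMap, geometry)
  attFac <- exp(-att@values)
  s <- radialOffsets(geometry)
  sMax <- max(abs(s))
  normProfile <- if (normAmplitude == 0 || sMax == 0) rep(1, length(s)) else
    1 + normAmplitude * cos(pi * s / sMax)
  normFac <- array(normProfile, dim = dim(proj@values))
  trues <- proj@values * attFac * normFac
  list(truesMean = sinogram(trues, geometry, "trues"),
       attenuation = sinogram(attFac, geometry, "attenuation_factors"),
       normalization = sinogram(normFac, geometry, "normalization_factors"),
       blurredUptake = blurred)
}

#' Expected randoms and scatter components
#'
#' Randoms are modelled as a uniform sinogram multiplied by the
#' normalization factors; scatter as a radially smoothed copy of the trues
#' sinogram (Gaussian, default 40 mm FWHM in the radial direction). The
#' scale constants are solved so the expected fractions match the
#' configured definitions exactly on the means: randoms fraction =
#' randoms / prompts, scatter fraction = scatter / (trues + scatter).
#'
#' @param truesMean expected trues [Sinogram-class].
#' @param normalization normalization-factor [Sinogram-class].
#' @param randomsFraction expected randoms / prompts (default 0.25).
#' @param scatterFraction expected scatter / (trues + scatter)
#'   (default 0.28).
#' @param scatterFwhmMm radial smoothing FWHM of the scatter model in mm.
#' @return list with `randomsMean` and `scatterMean` Sinograms.
#' @export
addBackgroundComponents <- function(truesMean, normalization,
                                    randomsFraction = 0.25,
                                    scatterFraction = 0.28,
                                    scatterFwhmMm = 40) {
  if (randomsFraction < 0 || randomsFraction >= 1 ||
      scatterFraction < 0 || scatterFraction >= 1)
    stop("fractions must lie in [0, 1)")
  geom <- truesMean@geometry
  T <- truesMean@values
  sumT <- sum(T)

  smooth <- T
  if (scatterFraction > 0 && sumT > 0) {
    B <- .gaussBand(geom@nRadial, scatterFwhmMm, geom@radialBinSize)
    d <- dim(T)
    flat <- matrix(T, nrow = d[1])
    smooth <- array(B %*% flat, dim = d)
  }
  sumS <- scatterFraction / (1 - scatterFraction) * sumT
  S <- if (sum(smooth) > 0) smooth * (sumS / sum(smooth)) else smooth * 0

  Rbase <- array(rep(normalization@values, length.out = length(T)), dim = dim(T))
  sumR <- randomsFraction / (1 - randomsFraction) * (sumT + sumS)
  R <- if (sum(Rbase) > 0) Rbase * (sumR / sum(Rbase)) else Rbase * 0

  list(randomsMean = sinogram(R, geom, "randoms"),
       scatterMean = sinogram(S, geom, "scatter"))
}

#' Draw one Poisson noise realization of the study
#'
#' All component means are rescaled so the expected total prompts equal
#' `totalPrompts`, then independent Poisson counts are drawn per bin for
#' trues, randoms and scatter, and summed into the prompts. The correction
#' set carries the (rescaled) known means: multiplicative = attenuation x
#' normalization, additive = expected randoms + scatter. Reproducible:
#' the same seed yields bit-identical sinograms.
#'
#' @param phantom output of [makePhantom()].
#' @param noiseFree output of [simulateNoiseFree()].
#' @param background output of [addBackgroundComponents()].
#' @param totalPrompts expected total prompt counts (default 1e6).
#' @param seed integer seed.
#' @return a [PhantomStudy-class].
#' @export
realizeStudy <- function(phantom, noiseFree, background,
                         totalPrompts = 1e6, seed = 1L) {
  if (totalPrompts <= 0) stop("totalPrompts must be > 0")
  geom <- noiseFree$truesMean@geometry
  Tm <- noiseFree$truesMean@values
  Rm <- background$randomsMean@values
  Sm <- background$scatterMean@values
  f <- totalPrompts / (sum(Tm) + sum(Rm) + sum(Sm))
  Tm <- Tm * f; Rm <- Rm * f; Sm <- Sm * f

  set.seed(as.integer(seed))
  trues <- array(stats::rpois(length(Tm), Tm), dim = dim(Tm))
  randoms <- array(stats::rpois(length(Rm), Rm), dim = dim(Rm))
  scatter <- array(stats::rpois(length(Sm), Sm), dim = dim(Sm))

  mult <- noiseFree$attenuation@values * noiseFree$normalization@values
  new("PhantomStudy", seed = as.integer(seed),
      prompts = sinogram(trues + randoms + scatter, geom, "prompts"),
      trues = sinogram(trues, geom, "trues"),
      randoms = sinogram(randoms, geom, "randoms"),
      scatter = sinogram(scatter, geom, "scatter"),
      corrections = correctionSet(
        sinogram(mult, geom, "normalization_factors"),
        sinogram(Rm + Sm, geom, "randoms")),
      groundTruth = phantom$uptake,
      roiMasks = phantom$roiMasks)
}

#' Default sinogram geometry for a phantom grid
#'
#' Radial bins of the clinical 2.045 mm sampling covering the grid
#' diagonal, and `nAngles` angles over [0, pi).
#'
#' @param grid phantom [ImageGrid-class].
#' @param nAngles number of angles (default 96).
#' @param radialBinSize radial bin size in mm (default 2.045).
#' @return a [SinogramGeometry-class].
#' @export
defaultGeometry <- function(grid, nAngles = 96L, radialBinSize = 2.045) {
  diag <- sqrt(sum(fovExtent(grid)[1:2]^2))
  nR <- as.integer(ceiling(diag / radialBinSize)) + 1L
  sinogramGeometry(nR, nAngles, radialBinSize,
                   if (length(grid@shape) == 3L) grid@shape[3] else 1L)
}
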