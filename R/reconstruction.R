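## MLEM and Green's one-step-late (OSL) MAP-EM. The forward model for the
## measured prompts m is q = A theta + a, with A the system operator
## (including the multiplicative attenuation x normalization factors) and a
## the expected additive background (randoms + scatter). The EM update is
##   theta <- theta / s * A'( m / (A theta + a) ),
## with s = A'(1) the sensitivity image; OSL adds beta * dU/dtheta evaluated
## at the previous iterate to the denominator s.

#' Construct a correction set
#'
#' @param multiplicative [Sinogram-class] of attenuation x normalization
#'   factors.
#' @param additive [Sinogram-class] of expected randoms + scatter.
#' @return a [CorrectionSet-class].
#' @export
correctionSet <- function(multiplicative, additive) {
  new("CorrectionSet", multiplicative = multiplicative, additive = additive)
}

.effectiveModel <- function(model, corrections) {
  if (is.null(corrections)) return(model)
  if (!is.null(model@multFactors))
    stop("multiplicative factors specified in both the model and the corrections")
  model@multFactors <- corrections@multiplicative
  model
}

#' EM sensitivity image
#'
#' Back-projection of the multiplicative correction factors (of a sinogram
#' of ones when there are none): the EM normalizer s = A'(1). Strictly
#' positive over the voxels any ray intersects; exactly zero outside, and
#' those voxels are frozen at zero by the reconstruction.
#'
#' @param model a [SystemModel-class].
#' @param corrections optional [CorrectionSet-class]; its multiplicative
#'   factors are composed into the model.
#' @return a [VolumeImage-class].
#' @export
sensitivityImage <- function(model, corrections = NULL) {
  model <- .effectiveModel(model, corrections)
  backProject(model, sinogram(1, model@geometry, role = "sensitivity"))
}

#' Mean sensitivity in the centre of the FOV (the beta0 scale basis)
#'
#' Mean of the sensitivity image over a central disc of radius a fraction
#' (default 25%) of the half-FOV. Candidate beta0 values are conventionally
#' 0.1, 0.2, 0.5, 1 and 2 times this value, which makes them independent of
#' the system matrix used (the penalty is additive to the sensitivity in
#' the OSL denominator).
#'
#' @param sens sensitivity [VolumeImage-class].
#' @param radiusFraction fraction of the half-FOV (default 0.25).
#' @return scalar mean sensitivity.
#' @export
centralSensitivity <- function(sens, radiusFraction = 0.25) {
  g <- sens@grid
  nd <- length(g@shape)
  ai <- arrayInd(seq_len(prod(g@shape)), g@shape)
  r2 <- 0
  for (ax in 1:2) r2 <- r2 + voxelCenters(g, ax)[ai[, ax]]^2
  rad <- radiusFraction * min(fovExtent(g)[1:2]) / 2
  mean(sens@values[r2 <= rad^2])
}

#' Candidate beta0 values from the sensitivity image
#'
#' @param sens sensitivity [VolumeImage-class].
#' @param multipliers multipliers of the central sensitivity mean
#'   (default 0.1, 0.2, 0.5, 1, 2).
#' @return named numeric vector of beta0 candidates.
#' @export
beta0Candidates <- function(sens, multipliers = c(0.1, 0.2, 0.5, 1, 2)) {
  s0 <- centralSensitivity(sens)
  stats::setNames(multipliers * s0, paste0("x", multipliers))
}

.poissonLogLik <- function(m, q) {
  ok <- q > 0
  sum(m[ok] * log(q[ok])) - sum(q)
}

## Shared EM engine. prior = NULL gives plain MLEM. With a prior, beta *
## (one-sided smoothed-Lange derivative at the previous iterate) is added to
## the sensitivity denominator (Green's OSL). The denominator is floored at
## 1e-3 x median positive sensitivity (negativity guard); if more than
## `abortFraction` of the supported voxels need flooring the hyperparameters
## are too large for OSL and the run aborts with a diagnostic.
.emEngine <- function(prompts, model, corrections, nIter, init, prior,
                      saveEvery, symmetrized = FALSE, abortFraction = 0.01,
                      verbose = FALSE) {
  if (nIter < 1L) stop("nIter must be >= 1")
  model <- .effectiveModel(model, corrections)
  m <- prompts@values
  if (any(m < 0)) stop("prompts must be non-negative")
  addArr <- if (is.null(corrections)) array(0, dim = dim(m)) else
    corrections@additive@values
  sens <- backProject(model, sinogram(1, model@geometry, "sensitivity"))
  s <- sens@values
  mask <- s > 0
  if (!any(mask)) stop("sensitivity image is zero everywhere")
  sMed <- stats::median(s[mask])
  floorVal <- 1e-3 * sMed

  grid <- model@reconGrid
  if (is.null(init)) {
    c0 <- (sum(m) - sum(addArr)) / sum(s)
    if (!is.finite(c0) || c0 <= 0) {
      if (sum(m) == 0) {  # all-zero prompts: the ML solution is zero
        zero <- volumeImage(0, grid)
        return(new("ReconstructionTrace", iterates = list(), schedule = integer(),
                   logLik = numeric(), objective = numeric(),
                   flags = list(guardActivations = integer(nIter),
                                frozenVoxels = sum(!mask)),
                   final = zero))
      }
      c0 <- sum(m) / sum(s)
    }
    theta <- array(0, dim = grid@shape)
    theta[mask] <- c0
  } else {
    theta <- init@values
    if (any(theta < 0)) stop("init must be non-negative")
    theta[!mask] <- 0
  }

  schedule <- if (is.null(saveEvery)) nIter else
    unique(c(seq(saveEvery, nIter, by = saveEvery), nIter))
  logLik <- objective <- rep(NA_real_, length(schedule))
  iterates <- vector("list", length(schedule))
  guard <- integer(nIter)

  for (it in seq_len(nIter)) {
    q <- forwardProject(model, volumeImage(theta, grid))@values + addArr
    ratio <- array(0, dim = dim(q))
    pos <- q > 0
    ratio[pos] <- m[pos] / q[pos]
    corr <- backProject(model, sinogram(ratio, model@geometry))@values

    denom <- s
    if (!is.null(prior) && prior@beta > 0) {
      g <- cpp_smoothed_lange(as.numeric(theta), prior@gridShape,
                              prior@neighborhood@offsets, prior@xiRaw,
                              prior@w, prior@delta,
                              if (symmetrized) 1L else 0L)$grad
      denom <- s + prior@beta * array(g, dim = dim(s))
      bad <- mask & denom < floorVal
      guard[it] <- sum(bad)
      if (guard[it] > abortFraction * sum(mask))
        stop(sprintf(paste0("OSL denominator non-positive for %d of %d ",
                            "supported voxels at iteration %d: beta (%.4g) ",
                            "too large for one-step-late convergence"),
                     guard[it], sum(mask), it, prior@beta))
      denom[bad] <- floorVal
    }
    thetaNew <- array(0, dim = dim(theta))
    thetaNew[mask] <- theta[mask] * corr[mask] / denom[mask]
    theta <- thetaNew

    at <- match(it, schedule)
    if (!is.na(at)) {
      qNew <- forwardProject(model, volumeImage(theta, grid))@values + addArr
      ll <- .poissonLogLik(m, qNew)
      logLik[at] <- ll
      objective[at] <- if (is.null(prior) || prior@beta == 0) ll else
        ll - prior@beta * cpp_smoothed_lange(
          as.numeric(theta), prior@gridShape, prior@neighborhood@offsets,
          prior@xiRaw, prior@w, prior@delta, 0L)$energy
      iterates[[at]] <- volumeImage(theta, grid)
      if (verbose)
        message(sprintf("iter %d: logLik %.6f", it, ll))
    }
  }
  new("ReconstructionTrace", iterates = iterates,
      schedule = as.integer(schedule), logLik = logLik, objective = objective,
      flags = list(guardActivations = guard, frozenVoxels = sum(!mask)),
      final = volumeImage(theta, grid))
}

#' Maximum-likelihood EM reconstruction (MLEM)
#'
#' Standard EM for Poisson emission data with multiplicative and additive
#' corrections: theta <- theta / s * A'( m / (A theta + a) ). Iterates are
#' non-negative and the Poisson log-likelihood is non-decreasing. Voxels
#' with zero sensitivity (no ray coverage) are frozen at zero. No subsets
#' are used.
#'
#' @param prompts measured [Sinogram-class] (non-negative).
#' @param model a [SystemModel-class].
#' @param corrections optional [CorrectionSet-class].
#' @param nIter number of iterations (>= 1).
#' @param init optional non-negative initial [VolumeImage-class]; the
#'   default is a uniform positive image scaled to match the total counts.
#' @param saveEvery save an iterate (and the log-likelihood) every this
#'   many iterations; NULL keeps only the final iterate.
#' @param verbose print the log-likelihood at saved iterations.
#' @return a [ReconstructionTrace-class].
#' @export
mlem <- function(prompts, model, corrections = NULL, nIter = 100L,
                 init = NULL, saveEvery = NULL, verbose = FALSE) {
  .emEngine(prompts, model, corrections, as.integer(nIter), init,
            prior = NULL, saveEvery = saveEvery, verbose = verbose)
}

#' One-step-late MAP-EM with the smoothed Lange prior (Green's OSL)
#'
#' The MLEM denominator is augmented with the penalty derivative evaluated
#' at the previous iterate: theta <- theta / (s + beta dU(theta_prev)) *
#' A'( m / (A theta + a) ). With beta = 0 the trajectory equals [mlem()]
#' exactly. OSL converges to the MAP solution only when beta is small
#' enough to keep the denominator positive; denominators below 1e-3 x the
#' median sensitivity are floored (and counted in the trace flags), and the
#' run aborts when more than 1% of supported voxels violate positivity.
#'
#' @inheritParams mlem
#' @param prior a [PriorModel-class] on the model's reconstruction grid.
#' @param symmetrized use the symmetrized penalty derivative instead of the
#'   printed one-sided form (default FALSE).
#' @return a [ReconstructionTrace-class].
#' @export
oslMapem <- function(prompts, model, corrections = NULL, prior, nIter = 100L,
                     init = NULL, saveEvery = NULL, symmetrized = FALSE,
                     verbose = FALSE) {
  if (!identical(prior@gridShape, as.integer(model@reconGrid@shape)))
    stop("prior was not built on the model's reconstruction grid")
  .emEngine(prompts, model, corrections, as.integer(nIter), init,
            prior = prior, saveEvery = saveEvery, symmetrized = symmetrized,
            verbose = verbose)
}

#' Clinical-style comparator reconstruction
#'
#' MLEM stopped early (60 iterations without PSF modelling, 80 with,
#' broadly equivalent to 3-4 iterations with 21 subsets) followed by a
#' Gaussian post-filter (default 4 mm FWHM), mimicking how scanners are
#' operated clinically. Provided as a utility comparator; no claim of
#' vendor-exact output is made.
#'
#' @inheritParams mlem
#' @param postFilterFwhmMm post-smoothing FWHM in mm (default 4).
#' @return a [ReconstructionTrace-class] whose `final` is post-filtered.
#' @export
clinicalMlem <- function(prompts, model, corrections = NULL,
                         nIter = if (length(model@blur)) 80L else 60L,
                         postFilterFwhmMm = 4) {
  tr <- mlem(prompts, model, corrections, nIter = nIter)
  tr@final <- psfBlur(tr@final, postFilterFwhmMm)
  tr
}
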