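# EM reconstruction properties: sensitivity, fixed point, likelihood
# monotonicity, OSL behaviour and safeguards.

test_that("the sensitivity image is the adjoint applied to the factors", {
  g <- imageGrid(c(8, 8), 1)
  geom <- sinogramGeometry(10, 12, 1.37)
  set.seed(21)
  mfArr <- array(runif(120, 0.5, 1.5), c(10, 12))
  model <- buildSystemModel(g, geom)
  corr <- correctionSet(sinogram(mfArr, geom, "normalization_factors"),
                        sinogram(0, geom, "randoms"))
  s <- sensitivityImage(model, corr)
  A <- denseSystemMatrix(g, geom)
  expect_lt(max(abs(as.numeric(values(s)) -
                    crossprod(A, as.numeric(mfArr)))), 1e-10)
  # unit factors, symmetric geometry: centrally symmetric image
  s1 <- values(sensitivityImage(model))
  expect_equal(s1, s1[8:1, 8:1], tolerance = 1e-9)
  expect_error(sensitivityImage(buildSystemModel(g, geom, multFactors =
    corr@multiplicative), corr), "both")
})

test_that("beta0 candidates scale the central sensitivity mean", {
  g <- imageGrid(c(16, 16), 2)
  model <- buildSystemModel(g, sinogramGeometry(24, 16))
  sens <- sensitivityImage(model)
  b0 <- beta0Candidates(sens)
  expect_equal(unname(b0 / centralSensitivity(sens)),
               c(0.1, 0.2, 0.5, 1, 2))
})

test_that("noise-free uniform data is an EM fixed point", {
  g <- imageGrid(c(12, 12), 2)
  geom <- sinogramGeometry(20, 16)
  model <- buildSystemModel(g, geom)
  truth <- volumeImage(3, g)
  prompts <- forwardProject(model, truth)
  prompts@role <- "prompts"
  tr <- mlem(prompts, model, nIter = 1, init = truth)
  s <- values(sensitivityImage(model))
  expect_lt(max(abs(values(tr@final) - values(truth))[s > 0]), 1e-10)
})

test_that("the Poisson log-likelihood is non-decreasing over MLEM iterations", {
  st <- smallStudy(counts = 1e5)
  grid <- imageGrid(c(48, 48), 2)
  model <- buildSystemModel(grid, st$geom, psfFwhmMm = 2.5)
  tr <- mlem(st$study@prompts, model, st$study@corrections, nIter = 25,
             saveEvery = 1)
  expect_true(all(diff(tr@logLik) >= -1e-9 * abs(tr@logLik[1])))
  expect_true(all(vapply(tr@iterates, function(im) all(values(im) >= 0),
                         logical(1))))
})

test_that("OSL with beta = 0 reproduces MLEM exactly", {
  st <- smallStudy(counts = 5e4)
  grid <- imageGrid(c(32, 32), 3)
  model <- buildSystemModel(grid, st$geom)
  pr <- priorModel(grid, delta = 1, beta = 0)
  a <- mlem(st$study@prompts, model, st$study@corrections, nIter = 8)
  b <- oslMapem(st$study@prompts, model, st$study@corrections, pr, nIter = 8)
  expect_identical(values(a@final), values(b@final))
})

test_that("a noise-free identifiable problem is recovered to < 1% NRMSE", {
  g <- imageGrid(c(8, 8), 1)
  geom <- sinogramGeometry(12, 14, 1.19)   # 168 rays > 64 voxels
  A <- denseSystemMatrix(g, geom)
  expect_gte(qr(A)$rank, 64)               # identifiability (dense oracle)
  set.seed(22)
  truth <- array(runif(64, 1, 3), c(8, 8))
  model <- buildSystemModel(g, geom)
  prompts <- forwardProject(model, volumeImage(truth, g))
  prompts@role <- "prompts"
  tr <- mlem(prompts, model, nIter = 2000)
  nrmse <- sqrt(mean((values(tr@final) - truth)^2)) / mean(truth)
  expect_lt(nrmse, 0.01)
})

test_that("degenerate inputs are handled: zero prompts, uncovered voxels", {
  g <- imageGrid(c(10, 10), 2)
  geom <- sinogramGeometry(12, 8)
  model <- buildSystemModel(g, geom)
  z <- mlem(sinogram(0, geom, "prompts"), model, nIter = 3)
  expect_true(all(values(z@final) == 0))
  # radial coverage narrower than the FOV: outside voxels frozen at zero
  narrow <- sinogramGeometry(3, 3, radialBinSize = 1)
  gN <- imageGrid(c(12, 12), 2)
  modelN <- buildSystemModel(gN, narrow)
  s <- values(sensitivityImage(modelN))
  pr <- forwardProject(modelN, volumeImage(1, gN))
  pr@role <- "prompts"
  tr <- mlem(pr, modelN, nIter = 5)
  expect_true(all(values(tr@final)[s == 0] == 0))
  expect_gt(sum(s == 0), 0)
})

test_that("the negativity guard aborts on oversized beta with a diagnostic", {
  st <- smallStudy(counts = 5e4)
  grid <- imageGrid(c(32, 32), 3)
  model <- buildSystemModel(grid, st$geom)
  sens <- sensitivityImage(model, st$study@corrections)
  pr <- priorModel(grid, anatomical = interpolateToGrid(st$phantom$pseudoT1,
                                                        grid),
                   delta = 1e-4, beta = 100 * centralSensitivity(sens))
  expect_error(oslMapem(st$study@prompts, model, st$study@corrections, pr,
                        nIter = 30), "beta")
})

test_that("the clinical comparator post-smooths an early-stopped MLEM", {
  st <- smallStudy(counts = 1e5)
  grid <- imageGrid(c(48, 48), 2)
  model <- buildSystemModel(grid, st$geom)
  tr <- clinicalMlem(st$study@prompts, model, st$study@corrections, nIter = 10)
  raw <- mlem(st$study@prompts, model, st$study@corrections, nIter = 10)
  expect_equal(values(tr@final), values(psfBlur(raw@final, 4)))
  roi <- values(raw@final) > 0
  expect_lt(sd(values(tr@final)[roi]), sd(values(raw@final)[roi]))
})

test_that("fine-lattice ray undersampling pins gap voxels that D repairs", {
  # thin rays at 2.045 mm pitch on a 0.5 mm lattice leave voxels uncovered;
  # the composed model reconstructs the disc intact
  res <- fineGridArtifactDemo(fineVoxelMm = 0.5, fovMm = 96,
                              discRadiusMm = 36, interiorRadiusMm = 25,
                              nAngles = 64, counts = 5e6, nIter = 150,
                              seed = 3)
  plain <- res[res$model == "plain", ]
  comp <- res[res$model == "composed", ]
  expect_lt(plain$minToMean, 0.05)   # gap voxels collapse towards zero
  expect_gt(comp$minToMean, 0.5)     # composed model has no gaps
  expect_gt(plain$fracBelowHalf, comp$fracBelowHalf)
})

test_that("PSF-MLEM overshoots at hot-structure rims; MR guidance suppresses it", {
  g <- imageGrid(c(96, 96), 1)
  xs <- voxelCenters(g, 1)
  r2 <- outer(xs^2, xs^2, `+`)
  truth <- array(1, c(96, 96))
  truth[r2 <= 6^2] <- 4                       # small hot disc, contrast 4
  disc <- r2 <= 5^2
  geom <- defaultGeometry(g, 96)
  prompts <- siddonForward(psfBlur(volumeImage(truth, g), 4.3), geom)
  prompts@role <- "prompts"
  model <- buildSystemModel(g, geom, psfFwhmMm = 4.5)
  trM <- mlem(prompts, model, nIter = 100)
  overM <- max(values(trM@final)[disc]) / 4 - 1
  expect_gt(overM, 0.05)                      # Gibbs overshoot
  anat <- volumeImage(array(as.numeric(truth > 2), c(96, 96)), g)
  pilot <- mlem(prompts, model, nIter = 20)
  rule <- deltaRule(pilot@final)
  b0 <- centralSensitivity(sensitivityImage(model))
  pr <- priorModel(g, anatomical = anat, delta = rule$delta0,
                   beta = scaleBeta(rule$delta0, rule$delta0, 0.1 * b0,
                                    rule$dynamicRange))
  trG <- oslMapem(prompts, model, prior = pr, nIter = 100)
  overG <- max(values(trG@final)[disc]) / 4 - 1
  expect_lt(overG, 0.02)                      # suppressed by MR guidance
  expect_lt(overG, overM)
})
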