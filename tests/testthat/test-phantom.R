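# Phantom construction and the emission-data simulator: label structure,
# uptake and attenuation constraints, correction factors, background
# component calibration and Poisson realizations.

test_that("the phantom partitions the grid with the configured tissue values", {
  ph <- makePhantom(phantomSpec())
  lab <- values(ph$labels)
  expect_true(all(lab %in% 0:8))            # every voxel exactly one class
  masks <- ph$roiMasks
  expect_true(all(vapply(masks, sum, numeric(1)) > 0))
  # gray-matter uptake is exactly 4x white matter, everywhere in GM
  up <- values(ph$uptake)
  expect_equal(unique(up[masks$grayAll]), 4)
  expect_equal(unique(up[masks$whiteMatter]), 1)
  expect_equal(mean(up[masks$grayAll]) / mean(up[masks$whiteMatter]), 4)
  # attenuation map uses exactly two non-zero tissue values
  mu <- values(ph$muMap)
  expect_equal(sort(setdiff(unique(as.numeric(mu)), 0)), c(0.0096, 0.0151))
  # pseudo-T1 separates the tissues it guides on (rank order)
  t1 <- values(ph$pseudoT1)
  expect_gt(mean(t1[masks$whiteMatter]), mean(t1[masks$corticalGM]))
  expect_gt(mean(t1[masks$corticalGM]), mean(t1[lab == 1]))  # GM > CSF
  # striatal structures are disjoint from cortical GM
  expect_equal(sum(masks$caudate & masks$corticalGM), 0)
})

test_that("attenuation factors are the exponentiated line integrals", {
  # 100 mm of soft tissue (mu = 0.0096/mm) -> exp(-0.96) on the axial ray
  g <- imageGrid(c(10, 10), 10)
  ray <- sinogramGeometry(1, 1, 5)
  fake <- list(uptake = volumeImage(1, g), muMap = volumeImage(0.0096, g))
  nf <- simulateNoiseFree(fake, ray, systemFwhmMm = 0, normAmplitude = 0)
  expect_equal(as.numeric(values(nf$attenuation)), exp(-0.96))
  # zero attenuation map: factors identically 1
  fake0 <- list(uptake = volumeImage(1, g), muMap = volumeImage(0, g))
  nf0 <- simulateNoiseFree(fake0, sinogramGeometry(8, 6), systemFwhmMm = 0)
  expect_true(all(values(nf0$attenuation) == 1))
  # linearity: doubling the uptake doubles the expected trues exactly
  fake2 <- list(uptake = volumeImage(2, g), muMap = volumeImage(0.0096, g))
  nf1 <- simulateNoiseFree(fake, sinogramGeometry(8, 6), systemFwhmMm = 4.3)
  nf2 <- simulateNoiseFree(fake2, sinogramGeometry(8, 6), systemFwhmMm = 4.3)
  expect_equal(values(nf2$truesMean), 2 * values(nf1$truesMean),
               tolerance = 1e-12)
})

test_that("background components reproduce the configured fractions exactly", {
  st <- smallStudy(counts = 1e5)
  sumT <- sum(values(st$noiseFree$truesMean))
  sumR <- sum(values(st$background$randomsMean))
  sumS <- sum(values(st$background$scatterMean))
  expect_lt(abs(sumR / (sumT + sumR + sumS) - 0.25), 1e-10)
  expect_lt(abs(sumS / (sumT + sumS) - 0.28), 1e-10)
  # zero fractions give zero background sinograms
  bg0 <- addBackgroundComponents(st$noiseFree$truesMean,
                                 st$noiseFree$normalization, 0, 0)
  expect_true(all(values(bg0$randomsMean) == 0))
  expect_true(all(values(bg0$scatterMean) == 0))
  expect_error(addBackgroundComponents(st$noiseFree$truesMean,
                                       st$noiseFree$normalization, 1, 0.28),
               "fractions")
})

test_that("the scatter model is radially smoother than the trues", {
  st <- smallStudy(counts = 1e5)
  highFreqPower <- function(sino) {
    v <- values(sino)
    p <- 0
    for (a in seq_len(ncol(v))) {
      sp <- Mod(fft(v[, a]))^2
      n <- length(sp)
      p <- p + sum(sp[seq(floor(n / 4), ceiling(3 * n / 4))])
    }
    p / sum(values(sino))^2
  }
  expect_lt(highFreqPower(st$background$scatterMean),
            highFreqPower(st$noiseFree$truesMean))
})

test_that("realizations are seeded, reproducible and calibrated", {
  st <- smallStudy(counts = 1e6, seed = 5)
  again <- realizeStudy(st$phantom, st$noiseFree, st$background, 1e6, 5)
  expect_identical(values(st$study@prompts), values(again@prompts))
  other <- realizeStudy(st$phantom, st$noiseFree, st$background, 1e6, 6)
  expect_false(identical(values(st$study@prompts), values(other@prompts)))
  # prompts decompose by construction
  expect_equal(values(st$study@prompts),
               values(st$study@trues) + values(st$study@randoms) +
                 values(st$study@scatter))
  # realized totals within 4 sigma of the target (Poisson sum)
  tot <- sum(values(st$study@prompts))
  expect_lt(abs(tot - 1e6), 4 * sqrt(1e6))
  # realized randoms fraction within 3 sigma (binomial error) of 25%
  rf <- sum(values(st$study@randoms)) / tot
  expect_lt(abs(rf - 0.25), 3 * sqrt(0.25 * 0.75 / 1e6))
  # corrections carry the rescaled means
  expect_equal(sum(values(st$study@corrections@additive)),
               0.25 * 1e6 + 0.28 * 0.75 * 1e6, tolerance = 1e-9)
})
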