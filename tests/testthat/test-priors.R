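# Lange potential, proximity and Bowsher weights, the smoothed Lange
# energy/gradient pair, and the beta scaling rule.

test_that("the Lange potential has its closed-form values and limits", {
  expect_equal(langePotential(0, 1), 0)
  expect_equal(langePotential(1, 1), 1 - log(2))
  expect_equal(langePotential(-1, 1), langePotential(1, 1))  # even
  # quadratic regime: psi(t) ~ t^2 / (2 delta) for |t| << delta
  d <- 2
  t <- d / 100
  expect_lt(abs(langePotential(t, d) - t^2 / (2 * d)) / (t^2 / (2 * d)), 0.01)
  # TV regime: psi(t)/|t| -> 1 for |t| >> delta
  expect_gt(langePotential(1000 * d, d) / (1000 * d), 0.99)
  tt <- seq(0, 5, by = 0.1)
  expect_true(all(diff(langePotential(tt, 1)) >= 0))  # monotone in |t|
  expect_error(langePotential(1, 0), "positive")
})

test_that("proximity weights are normalized inverse distances", {
  # 4-neighbourhood, isotropic voxels: all weights 1/4 by symmetry
  n4 <- new("Neighborhood",
            offsets = matrix(c(-1L, 0L, 0L, -1L, 0L, 1L, 1L, 0L),
                             ncol = 2, byrow = TRUE),
            distances = rep(1, 4), voxelSize = c(1, 1))
  expect_equal(proximityWeights(n4), rep(1 / 4, 4))
  # 8-neighbourhood, 1 mm voxels: hand computation
  n8 <- boxNeighborhood(3, c(1, 1))
  xi <- proximityWeights(n8)
  denom <- 4 + 4 / sqrt(2)
  axial <- abs(rowSums(abs(n8@offsets)) == 1)
  expect_equal(unname(xi[axial == 1]), rep(1 / denom, 4))
  expect_equal(unname(xi[axial == 0]), rep((1 / sqrt(2)) / denom, 4))
  expect_equal(sum(xi), 1)
  # anisotropic voxels: the short (1 mm) axis gets the larger weight
  na <- boxNeighborhood(3, c(2, 1))
  xia <- proximityWeights(na)
  wShort <- xia[na@offsets[, 1] == 0 & na@offsets[, 2] == 1]
  wLong <- xia[na@offsets[, 1] == 1 & na@offsets[, 2] == 0]
  expect_gt(wShort, wLong)
  expect_error(boxNeighborhood(2, 1), "odd")
})

test_that("neighbourhoods of fixed physical extent track the voxel size", {
  expect_equal(nrow(neighborhoodFromExtent(5, c(1, 1))@offsets), 24L)  # 5x5
  expect_equal(nrow(neighborhoodFromExtent(5, c(2, 2))@offsets), 8L)   # 3x3
  expect_equal(nrow(neighborhoodFromExtent(5, c(1, 1, 1))@offsets), 124L)
})

test_that("Bowsher selection keeps the B most similar neighbours", {
  g <- imageGrid(c(9, 9), 1)
  neigh <- boxNeighborhood(3, c(1, 1))
  # constant anatomical image, B = neighbourhood size: all in-bounds ones
  const <- volumeImage(1, g)
  wAll <- bowsherWeights(const, neigh, 8)
  inner <- as.numeric(matrix(seq_len(81), 9, 9)[2:8, 2:8])
  expect_true(all(rowSums(wAll[inner, ]) == 8))
  # boundary voxels select all available neighbours
  expect_equal(rowSums(wAll)[1], 3)       # corner has 3 in-bounds neighbours
  # constant image ties: smaller distance first (axial before diagonal),
  # then lexicographic offset order
  w4 <- bowsherWeights(const, neigh, 4)
  centre <- 5 + 4 * 9
  axial <- rowSums(abs(neigh@offsets)) == 1
  expect_equal(w4[centre, axial], rep(1L, 4))
  expect_equal(w4[centre, !axial], rep(0L, 4))
  w5 <- bowsherWeights(const, neigh, 5)
  diagIdx <- which(!axial)
  expect_equal(w5[centre, diagIdx[1]], 1L)     # first diagonal in lex order
  expect_equal(sum(w5[centre, diagIdx[-1]]), 0L)
  # two-region step: near-boundary voxels select only their own side
  step <- volumeImage(array(rep(c(0, 0, 0, 0, 10, 10, 10, 10, 10),
                                each = 9), c(9, 9)), g)
  wStep <- bowsherWeights(step, neigh, 3)
  for (i in 2:8) for (j in c(4, 5)) {         # columns flanking the step
    v <- i + (j - 1) * 9
    sameSide <- (step@values[cbind(i + neigh@offsets[, 1],
                                   j + neigh@offsets[, 2])] ==
                 step@values[i, j])
    expect_true(all(sameSide[wStep[v, ] == 1]))
  }
  expect_error(bowsherWeights(const, neigh, 9), "neighbourhood size")
})

test_that("smoothed Lange energy matches hand evaluation and is monotone in w", {
  g <- imageGrid(c(5, 5), 1)
  neigh <- boxNeighborhood(3, c(1, 1))
  pr <- priorModel(g, neigh = neigh, delta = 0.7, beta = 1)
  expect_equal(smoothedLangeEnergy(volumeImage(3, g), pr), 0)
  # single spike h at the centre of a 5x5 zero image: hand computation
  h <- 2
  img <- volumeImage(0, g)
  v <- values(img); v[3, 3] <- h; values(img) <- v
  xi <- proximityWeights(neigh)              # interior normalization
  psi <- function(t) langePotential(t, 0.7)
  axialXi <- xi[rowSums(abs(neigh@offsets)) == 1][1]
  diagXi <- xi[rowSums(abs(neigh@offsets)) == 2][1]
  expected <- psi(h) +                        # the spike voxel itself (sum xi = 1)
    4 * psi(h * sqrt(axialXi)) + 4 * psi(h * sqrt(diagXi))
  expect_equal(smoothedLangeEnergy(img, pr), expected, tolerance = 1e-12)
  # Bowsher masking can only decrease the energy (fewer penalized terms)
  set.seed(13)
  anat <- volumeImage(array(rnorm(25), c(5, 5)), g)
  noisy <- volumeImage(array(runif(25), c(5, 5)), g)
  prB <- priorModel(g, neigh = neigh, anatomical = anat, B = 3,
                    delta = 0.7, beta = 1)
  expect_gte(smoothedLangeEnergy(noisy, pr), smoothedLangeEnergy(noisy, prB))
})

test_that("within-region smoothing decreases the energy", {
  g <- imageGrid(c(8, 8), 1)
  set.seed(14)
  region <- array(rep(c(0, 5), each = 32), c(8, 8))
  anat <- volumeImage(region, g)
  pr <- priorModel(g, anatomical = anat, B = 3, delta = 0.5, beta = 1)
  noisy <- region + array(rnorm(64, 0, 0.3), c(8, 8))
  smoothItself <- region
  smoothItself[region == 0] <- mean(noisy[region == 0])
  smoothItself[region == 5] <- mean(noisy[region == 5])
  expect_lt(smoothedLangeEnergy(volumeImage(smoothItself, g), pr),
            smoothedLangeEnergy(volumeImage(noisy, g), pr))
})

test_that("the symmetrized gradient matches numeric differentiation", {
  g <- imageGrid(c(6, 6), 1)
  neigh <- boxNeighborhood(3, c(1, 1))
  set.seed(15)
  for (rep in 1:3) {
    anat <- volumeImage(array(rnorm(36), c(6, 6)), g)
    pr <- priorModel(g, neigh = neigh, anatomical = anat, B = 4,
                     delta = 0.8, beta = 1)
    th <- array(runif(36, 0.5, 2), c(6, 6))
    gr <- values(smoothedLangeGradient(volumeImage(th, g), pr,
                                       symmetrized = TRUE))
    eps <- 1e-6
    num <- th * 0
    for (k in seq_along(th)) {
      tp <- th; tp[k] <- tp[k] + eps
      tm <- th; tm[k] <- tm[k] - eps
      num[k] <- (smoothedLangeEnergy(volumeImage(tp, g), pr) -
                 smoothedLangeEnergy(volumeImage(tm, g), pr)) / (2 * eps)
    }
    expect_lt(max(abs(gr - num)) / max(abs(num)), 1e-5)
  }
})

test_that("the one-sided gradient is bounded by 1 for normalized weights", {
  g <- imageGrid(c(10, 10), 1)
  set.seed(16)
  pr <- priorModel(g, delta = 0.3, beta = 1)
  for (rep in 1:5) {
    th <- volumeImage(array(rnorm(100, 0, 10), c(10, 10)), g)
    expect_lte(max(abs(values(smoothedLangeGradient(th, pr)))), 1 + 1e-12)
  }
  expect_true(all(values(smoothedLangeGradient(volumeImage(4, g), pr)) == 0))
})

test_that("beta scales with delta through k(delta)", {
  expect_equal(scaleBeta(0.05, 0.05, 7, imageDynamicRange = 2), 7)  # k = 1
  # Delta_theta = 0.3, delta0 = 0.03, delta = 3: k = 0.33 / 3.3 = 0.1
  expect_equal(scaleBeta(3, 0.03, 1, imageDynamicRange = 1.2,
                         dynamicRangeFraction = 0.25), 0.1)
  ds <- seq(0.01, 5, by = 0.07)
  ks <- vapply(ds, function(d) scaleBeta(d, 0.03, 1, 1.2), numeric(1))
  expect_true(all(diff(ks) < 0))  # strictly decreasing in delta
  expect_error(scaleBeta(1, 0.1, 1, imageDynamicRange = 0), "positive")
  pilot <- volumeImage(array(seq(0, 2, length.out = 16), c(4, 4)),
                       imageGrid(c(4, 4), 1))
  rule <- deltaRule(pilot)
  expect_equal(rule$dtheta, 0.25 * 2)
  expect_equal(rule$delta0, 0.1 * 0.25 * 2)
})
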