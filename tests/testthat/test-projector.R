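# Ray tracing, interpolation operators, PSF blurring and the composed
# system matrix, checked against independent dense oracles and by
# adjoint/linearity properties.

oracleGrid <- imageGrid(c(8, 8), 1)
oracleGeom <- sinogramGeometry(10, 12, radialBinSize = 1.37)

test_that("forward projection equals chord lengths through simple fields", {
  gu <- imageGrid(c(10, 10), 10)                  # 100 mm FOV
  ray <- sinogramGeometry(1, 1, 5)                # one central axis ray
  expect_equal(as.numeric(values(siddonForward(volumeImage(1, gu), ray))), 100)
  geom <- sinogramGeometry(16, 8)
  expect_true(all(values(siddonForward(volumeImage(0, gu), geom)) == 0))
  # rays beyond the FOV are exactly zero
  far <- sinogramGeometry(4, 3, radialBinSize = 200)
  v <- values(siddonForward(volumeImage(1, gu), far))
  expect_true(all(v[c(1, 4), ] == 0))
  expect_error(siddonForward(volumeImage(1, gu), sinogramGeometry(4, 3, nPlanes = 2)),
               "plane")
})

test_that("forward and backward match the dense clipping oracle", {
  A <- denseSystemMatrix(oracleGrid, oracleGeom)
  set.seed(5)
  x <- array(rnorm(64), c(8, 8))
  fwd <- values(siddonForward(volumeImage(x, oracleGrid), oracleGeom))
  expect_lt(max(abs(as.numeric(fwd) - A %*% as.numeric(x))), 1e-10)
  y <- array(rnorm(120), c(10, 12))
  bwd <- values(siddonBackward(sinogram(y, oracleGeom), oracleGrid))
  expect_lt(max(abs(as.numeric(bwd) - crossprod(A, as.numeric(y)))), 1e-10)
  z <- values(siddonBackward(sinogram(0, oracleGeom), oracleGrid))
  expect_true(all(z == 0))
})

test_that("every system model configuration is self-adjoint to 1e-6", {
  set.seed(7)
  gstd <- imageGrid(c(10, 10), 2)
  ghr <- imageGrid(c(20, 20), 1)
  geom <- sinogramGeometry(14, 9, 2.045)
  mf <- sinogram(array(runif(14 * 9, 0.5, 1.5), c(14, 9)), geom,
                 "normalization_factors")
  configs <- list(
    buildSystemModel(gstd, geom),
    buildSystemModel(gstd, geom, psfFwhmMm = 4.5),
    buildSystemModel(gstd, geom, reconGrid = ghr),
    buildSystemModel(gstd, geom, psfFwhmMm = 4.5, reconGrid = ghr),
    buildSystemModel(gstd, geom, psfFwhmMm = 2.5, reconGrid = ghr,
                     multFactors = mf))
  for (model in configs) {
    n <- prod(model@reconGrid@shape)
    for (rep in 1:20) {
      x <- volumeImage(array(rnorm(n), model@reconGrid@shape),
                       model@reconGrid)
      y <- sinogram(array(rnorm(14 * 9), c(14, 9)), geom)
      lhs <- sum(values(forwardProject(model, x)) * values(y))
      rhs <- sum(values(x) * values(backProject(model, y)))
      expect_lt(relErr(lhs, rhs), 1e-6)
    }
  }
})

test_that("forward/backward are linear and preserve non-negativity", {
  set.seed(8)
  g <- imageGrid(c(12, 12), 1.5)
  geom <- sinogramGeometry(16, 7)
  model <- buildSystemModel(g, geom, psfFwhmMm = 3)
  a <- array(runif(144), c(12, 12)); b <- array(runif(144), c(12, 12))
  fa <- values(forwardProject(model, volumeImage(a, g)))
  fb <- values(forwardProject(model, volumeImage(b, g)))
  fab <- values(forwardProject(model, volumeImage(2 * a - 3 * b, g)))
  expect_equal(fab, 2 * fa - 3 * fb, tolerance = 1e-12)
  expect_true(all(fa >= 0))
  expect_true(all(values(backProject(model, sinogram(abs(fa), geom))) >= 0))
})

test_that("down-sampling preserves constants and matches its dense oracle", {
  hg <- imageGrid(c(6, 6), 1)
  lg <- imageGrid(c(3, 3), 2)
  expect_equal(as.numeric(values(downsampleImage(volumeImage(2.5, hg), lg))),
               rep(2.5, 9))
  # identical grids: identity map
  arr <- array(rnorm(36), c(6, 6))
  same <- downsampleImage(volumeImage(arr, hg), hg)
  expect_equal(values(same), arr, tolerance = 1e-12)
  Dor <- denseDownsampleMatrix(hg, lg)
  D <- as.matrix(downsampleMatrix(hg, lg))
  expect_lt(max(abs(D - Dor)), 1e-12)
  expect_error(downsampleImage(volumeImage(1, lg), hg), "wrong direction")
})

test_that("up-sampling is the exact transpose of down-sampling", {
  set.seed(9)
  hg <- imageGrid(c(6, 6), 1); lg <- imageGrid(c(3, 3), 2)
  xh <- volumeImage(array(rnorm(36), c(6, 6)), hg)
  yl <- volumeImage(array(rnorm(9), c(3, 3)), lg)
  lhs <- sum(values(downsampleImage(xh, lg)) * values(yl))
  rhs <- sum(values(xh) * values(upsampleTranspose(yl, hg)))
  expect_lt(relErr(lhs, rhs), 1e-12)
  expect_true(all(values(upsampleTranspose(volumeImage(0, lg), hg)) == 0))
  Dor <- denseDownsampleMatrix(hg, lg)
  up <- values(upsampleTranspose(yl, hg))
  expect_lt(max(abs(as.numeric(up) - crossprod(Dor, as.numeric(values(yl))))),
            1e-12)
})

test_that("PSF blur has the requested width, unit gain and self-adjointness", {
  g <- imageGrid(c(101, 101), 1)
  pt <- volumeImage(0, g)
  v <- values(pt); v[51, 51] <- 1; values(pt) <- v
  expect_identical(values(psfBlur(pt, 0)), values(pt))
  b <- psfBlur(pt, 4.3)
  expect_lt(abs(sum(values(b)) - 1), 1e-6)           # unit-sum kernel
  expect_lt(abs(momentFwhm(values(b)[, 51]) - 4.3) / 4.3, 0.02)
  expect_lt(abs(momentFwhm(values(b)[51, ]) - 4.3) / 4.3, 0.02)
  set.seed(10)
  x <- volumeImage(array(rnorm(101^2), c(101, 101)), g)
  y <- volumeImage(array(rnorm(101^2), c(101, 101)), g)
  expect_lt(relErr(sum(values(psfBlur(x, 4.3)) * values(y)),
                   sum(values(x) * values(psfBlur(y, 4.3)))), 1e-12)
  expect_error(psfBlur(pt, -1), ">= 0")
})

test_that("the composed model reduces to plain Siddon in standard mode", {
  g <- imageGrid(c(10, 10), 2)
  geom <- sinogramGeometry(12, 6)
  model <- buildSystemModel(g, geom, psfFwhmMm = 0)
  x <- volumeImage(array(runif(100), c(10, 10)), g)
  expect_identical(values(forwardProject(model, x)),
                   values(siddonForward(x, geom)))
  expect_error(buildSystemModel(g, geom, reconGrid = imageGrid(c(5, 5), 4)),
               "coarser")
})

test_that("patch singular values match a direct dense SVD", {
  model <- buildSystemModel(oracleGrid, oracleGeom)
  sv <- patchSingularValues(model, 4)  # central 4x4 mm patch
  A <- denseSystemMatrix(oracleGrid, oracleGeom)
  xc <- voxelCenters(oracleGrid, 1)
  sel <- which(outer(abs(xc) <= 2 + 1e-9, abs(xc) <= 2 + 1e-9, `&`))
  svOracle <- sort(svd(A[, sel], nu = 0, nv = 0)$d, decreasing = TRUE)
  expect_equal(length(sv), length(sel))
  expect_lt(max(abs(sv - svOracle)), 1e-8)
  expect_error(patchSingularValues(model, 4, maxColumns = 2L), "too large")
})

test_that("3-D volumes project as independent axial planes", {
  g3 <- imageGrid(c(8, 8, 3), 1)
  geom3 <- sinogramGeometry(10, 6, 1.37, nPlanes = 3L)
  set.seed(12)
  arr <- array(runif(8 * 8 * 3), c(8, 8, 3))
  s3 <- values(siddonForward(volumeImage(arr, g3), geom3))
  g2 <- imageGrid(c(8, 8), 1)
  geom2 <- sinogramGeometry(10, 6, 1.37)
  for (k in 1:3)
    expect_equal(s3[, , k],
                 values(siddonForward(volumeImage(arr[, , k], g2), geom2)))
  x <- volumeImage(array(rnorm(192), c(8, 8, 3)), g3)
  y <- sinogram(array(rnorm(180), c(10, 6, 3)), geom3)
  expect_lt(relErr(sum(values(siddonForward(x, geom3)) * values(y)),
                   sum(values(x) * values(siddonBackward(y, g3)))), 1e-12)
})
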