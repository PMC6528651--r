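# Independent oracles used across the test files. These deliberately avoid
# the package's traversal code paths: the dense system matrix clips each ray
# against every pixel separately (Liang-Barsky), and the dense interpolation
# matrix is assembled by a direct per-voxel weight loop.

# Dense intersection-length matrix (rows: radial-fastest sinogram bins,
# columns: column-major voxels) by per-pixel line clipping.
denseSystemMatrix <- function(grid, geom) {
  s <- radialOffsets(geom)
  ang <- projectionAngles(geom)
  nx <- grid@shape[1]; ny <- grid@shape[2]
  xc <- voxelCenters(grid, 1); yc <- voxelCenters(grid, 2)
  dx <- grid@voxelSize[1]; dy <- grid@voxelSize[2]
  A <- matrix(0, length(s) * length(ang), nx * ny)
  for (ai in seq_along(ang)) {
    cphi <- cos(ang[ai]); sphi <- sin(ang[ai])
    d <- c(-sphi, cphi)
    for (ri in seq_along(s)) {
      p0 <- c(s[ri] * cphi, s[ri] * sphi)
      row <- ri + (ai - 1L) * length(s)
      for (j in seq_len(ny)) for (i in seq_len(nx)) {
        tlo <- -Inf; thi <- Inf; ok <- TRUE
        lo <- c(xc[i] - dx / 2, yc[j] - dy / 2)
        hi <- c(xc[i] + dx / 2, yc[j] + dy / 2)
        for (ax in 1:2) {
          if (abs(d[ax]) < 1e-14) {
            if (p0[ax] <= lo[ax] || p0[ax] >= hi[ax]) { ok <- FALSE; break }
          } else {
            t1 <- (lo[ax] - p0[ax]) / d[ax]
            t2 <- (hi[ax] - p0[ax]) / d[ax]
            tlo <- max(tlo, min(t1, t2)); thi <- min(thi, max(t1, t2))
          }
        }
        if (ok && thi > tlo) A[row, i + (j - 1L) * nx] <- thi - tlo
      }
    }
  }
  A
}

# Dense down-sampling matrix with bilinear weights computed from the
# high-resolution voxel coordinates, rows then normalized to sum 1.
denseDownsampleMatrix <- function(hrGrid, lrGrid) {
  nxl <- lrGrid@shape[1]; nyl <- lrGrid@shape[2]
  nxh <- hrGrid@shape[1]; nyh <- hrGrid@shape[2]
  D <- matrix(0, nxl * nyl, nxh * nyh)
  xcl <- voxelCenters(lrGrid, 1); ycl <- voxelCenters(lrGrid, 2)
  for (jh in seq_len(nyh)) for (ih in seq_len(nxh)) {
    x <- voxelCenters(hrGrid, 1)[ih]; y <- voxelCenters(hrGrid, 2)[jh]
    fx <- (x - lrGrid@origin[1]) / lrGrid@voxelSize[1]
    fy <- (y - lrGrid@origin[2]) / lrGrid@voxelSize[2]
    i0 <- floor(fx); ax <- fx - i0
    j0 <- floor(fy); ay <- fy - j0
    if (i0 < 0) { i0 <- 0; ax <- 0 }
    if (i0 > nxl - 2) { i0 <- nxl - 2; ax <- 1 }
    if (j0 < 0) { j0 <- 0; ay <- 0 }
    if (j0 > nyl - 2) { j0 <- nyl - 2; ay <- 1 }
    col <- ih + (jh - 1L) * nxh
    w <- c((1 - ax) * (1 - ay), ax * (1 - ay), (1 - ax) * ay, ax * ay)
    rows <- c(i0 + 1 + j0 * nxl, i0 + 2 + j0 * nxl,
              i0 + 1 + (j0 + 1) * nxl, i0 + 2 + (j0 + 1) * nxl)
    for (k in 1:4) D[rows[k], col] <- D[rows[k], col] + w[k]
  }
  rs <- rowSums(D); rs[rs == 0] <- 1
  D / rs
}

# Gaussian FWHM of a 1-D profile from its second moment.
momentFwhm <- function(profile, spacing = 1) {
  x <- seq_along(profile)
  m <- sum(x * profile) / sum(profile)
  s2 <- sum((x - m)^2 * profile) / sum(profile)
  2 * sqrt(2 * log(2)) * sqrt(s2) * spacing
}

# Small noisy 2-D study shared by reconstruction tests: brain phantom at
# 96 mm FOV (structures clipped by the FOV but label structure intact),
# 48 angles, modest counts.
smallStudy <- function(n = 96L, counts = 2e5, seed = 11L, nAngles = 48L) {
  ph <- makePhantom(phantomSpec(n = n))
  geom <- defaultGeometry(ph$uptake@grid, nAngles)
  nf <- simulateNoiseFree(ph, geom)
  bg <- addBackgroundComponents(nf$truesMean, nf$normalization)
  list(phantom = ph, geom = geom, noiseFree = nf, background = bg,
       study = realizeStudy(ph, nf, bg, counts, seed))
}

relErr <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
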