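noisefreeVP <- function(seed = 1, vox = c(0.33, 0.123, 0.123), ...)
  volumeParams(seed = seed, voxelSize = vox, psfSigma = c(0, 0, 0),
               noiseModel = list(gaussian_sd = 0, poisson_scale = 0), ...)

test_that("IsoData threshold solves the symmetric two-level case", {
  expect_equal(isodataThreshold(c(rep(10, 50), rep(90, 50))), 50)
  expect_error(isodataThreshold(rep(5, 100)), "constant")
})

test_that("IsoData agrees with the exhaustive fixed-point search", {
  set.seed(21)
  for (i in 1:25) {
    x <- c(rnorm(2000, 20, 10), rnorm(500, 150 + 30 * runif(1), 25))
    T <- isodataThreshold(x)
    fp <- isodataFixedPoints(x)
    expect_gte(length(fp), 1)
    expect_lte(min(abs(fp - T)), 1e-4 * diff(range(x)))
  }
})

test_that("IsoData lands between bimodal Gaussian peaks", {
  set.seed(4)
  x <- c(rnorm(3000, 20, 10), rnorm(1000, 200, 10))
  T <- isodataThreshold(x)
  expect_gt(T, 50); expect_lt(T, 170)
})

test_that("flood-fill labelling matches brute-force 26-connectivity", {
  set.seed(8)
  for (p in c(0.08, 0.2, 0.35)) {
    m <- array(runif(14^3) < p, c(14, 14, 14))
    lab <- calyxSFR:::cpp_label3d(m, dim(m))
    expect_identical(as.integer(lab), as.integer(bruteLabel3d(m)))
  }
  ## corner-touching blobs are one 26-connected cluster
  m <- array(FALSE, c(6, 6, 6))
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE
  expect_equal(max(calyxSFR:::cpp_label3d(m, dim(m))), 1L)
  ## blobs separated by 2 voxels stay distinct
  m2 <- array(FALSE, c(8, 8, 8))
  m2[2, 2, 2] <- TRUE; m2[2, 2, 5] <- TRUE
  expect_equal(max(calyxSFR:::cpp_label3d(m2, dim(m2))), 2L)
})

test_that("cluster labelling discards specks and keeps labels dense", {
  set.seed(5)
  a <- array(0, c(20, 20, 20))
  a[4:9, 4:9, 4:9] <- 100          # 216 voxels
  a[15, 15, 15] <- 100             # single-voxel speck
  a[14:16, 3:6, 14:16] <- 100      # 36 voxels
  vol <- new("VoxelVolume", intensities = a + rnorm(8000, 0, 1),
             voxelSize = c(0.1, 0.1, 0.1), channelName = "marker")
  cs <- floodfillClusters(vol, threshold = 50, minVoxels = 10L)
  expect_equal(length(cs@voxelCounts), 2L)
  expect_setequal(sort(cs@voxelCounts), c(36L, 216L))
  expect_equal(sort(unique(as.integer(cs@labels))), 0:2)
})

test_that("binary masks are invariant under intensity scaling", {
  set.seed(6)
  a <- array(c(rnorm(3000, 20, 5), rnorm(1096, 120, 15)), c(16, 16, 16))
  vol <- function(x) new("VoxelVolume", intensities = x,
                         voxelSize = c(0.1, 0.1, 0.1), channelName = "m")
  c1 <- floodfillClusters(vol(a), minVoxels = 5L)
  c2 <- floodfillClusters(vol(a * 7.3), minVoxels = 5L)
  expect_identical(c1@labels, c2@labels)
})

test_that("the distance transform matches brute force on anisotropic grids", {
  set.seed(9)
  sp <- c(0.11, 0.041, 0.041)
  for (i in 1:5) {
    m <- array(runif(10 * 11 * 12) < 0.1, c(10, 11, 12))
    if (!any(m)) m[5, 5, 5] <- TRUE
    d1 <- calyxSFR:::cpp_edt3d(m, dim(m), sp)
    expect_equal(as.numeric(d1), as.numeric(bruteEDT(m, sp)), tolerance = 1e-9)
  }
})

test_that("dilation is the identity at zero and monotone in distance", {
  m <- array(FALSE, c(9, 21, 21))
  m[5, 11, 11] <- TRUE
  soma <- new("SomaMask", mask = m, voxelSize = c(0.110, 0.041, 0.041),
              surfaceArea = NA_real_, dilationUsed = 0)
  expect_identical(maskArray(dilateSoma(soma, 0)), m)
  d1 <- dilateSoma(soma, 0.12)
  d2 <- dilateSoma(soma, 0.3)
  expect_true(all(maskArray(d1)[maskArray(soma)]))
  expect_true(all(maskArray(d2)[maskArray(d1)]))
  ## enumerated voxel distances at 0.12 um: +-2 lateral in-plane voxels
  ## (0.082), lateral diagonals up to (2,2) (0.116) and the +-1 axial
  ## neighbour (0.110) are all within range; (0,0,3) at 0.123 is not
  got <- maskArray(d1)
  expect_true(got[6, 11, 11])    # axial +1: 0.110 <= 0.12
  expect_true(got[5, 13, 11])    # lateral +2: 0.082
  expect_true(got[5, 13, 13])    # lateral (2,2): 0.116
  expect_false(got[5, 14, 11])   # lateral +3: 0.123 > 0.12
  expect_false(got[6, 12, 12])   # axial+diagonal: 0.124 > 0.12
})

test_that("the sphere probe segments a solid ball and rejects empty volumes", {
  vox <- c(0.2, 0.1, 0.1)
  d <- c(31, 61, 61)
  zc <- (seq_len(d[1]) - 16) * vox[1]
  yc <- (seq_len(d[2]) - 31) * vox[2]
  xc <- (seq_len(d[3]) - 31) * vox[3]
  rho <- sqrt(outer(outer(zc^2, yc^2, "+"), xc^2, "+")); dim(rho) <- d
  a <- ifelse(rho <= 2, 100, 0)
  vol <- new("VoxelVolume", intensities = a, voxelSize = vox, channelName = "fill")
  soma <- sphereFloodfill(vol, radius = 0.4, threshold = 50)
  ## interior voxels >= 0.4 um inside the ball must be included
  expect_true(all(maskArray(soma)[rho <= 1.6]))
  ## nothing outside the ball by more than the probe radius
  expect_false(any(maskArray(soma)[rho > 2.45]))
  empty <- new("VoxelVolume", intensities = array(0 * a + 1, d) +
                 array(rnorm(prod(d)), d) * 0.01,
               voxelSize = vox, channelName = "fill")
  expect_error(sphereFloodfill(empty, threshold = 50), "empty soma")
})

test_that("noisy somata are recovered within 10% of their true volume", {
  ## noise SD is 20% of the signal plateau; the probe criterion plus PSF
  ## carry a small outward bias, so the relative error shrinks with radius
  cell <- makeTestCell(10, soma = 4)
  for (s in 1:3) {
    vp <- volumeParams(seed = s, voxelSize = c(0.33, 0.123, 0.123),
                       psfSigma = c(0.2, 0.08, 0.08),
                       noiseModel = list(gaussian_sd = 20, poisson_scale = 0.5))
    vol <- synthVolume(cell, vp, minCapArea = 1e6)  # no caps
    soma <- sphereFloodfill(vol$fill)
    trueVol <- 4 / 3 * pi * 4^3
    measured <- sum(maskArray(soma)) * prod(voxelSize(soma))
    expect_lte(abs(measured - trueVol) / trueVol, 0.10)
  }
})

test_that("contact accounting satisfies its structural invariants", {
  cell <- makeTestCell(c(20, 10, 5), soma = 4)
  vol <- synthVolume(cell, noisefreeVP(seed = 3), minCapArea = 0.3)
  soma <- sphereFloodfill(vol$fill, threshold = 50)
  cl <- floodfillClusters(vol$marker, threshold = 50)
  rep <- contactReport(dilateSoma(soma, 0.35), cl)
  expect_equal(rep@totalContactArea, sum(rep@clusterArea), tolerance = 1e-9)
  expect_gte(rep@coverageFraction, 0)
  expect_lte(rep@coverageFraction, 1)
  expect_gt(rep@contactRatio, 0)
  expect_lte(rep@contactRatio, 1)
  expect_equal(rep@largestArea, max(rep@clusterArea))
  ## a cluster nowhere near the soma reports zero contact
  far <- array(0L, dim(cl@labels))
  far[2:4, 2:4, 2:4] <- 1L
  farSet <- new("ClusterSet", labels = far, voxelCounts = 27L,
                thresholdUsed = 50, voxelSize = cl@voxelSize)
  rep0 <- contactReport(dilateSoma(soma, 0.2), farSet)
  expect_equal(rep0@totalContactArea, 0)
})

test_that("measured cap areas track analytic truth and their ratios", {
  cell <- makeTestCell(c(6.8 * 30^0.35, 6.8 * 8^0.35, 6.8 * 2^0.35), soma = 5)
  vol <- synthVolume(cell, noisefreeVP(seed = 6), minCapArea = 0.3)
  seg <- segmentCell(vol$fill, vol$marker, step = 0.123)
  meas <- sort(clusterAreas(seg$report), decreasing = TRUE)
  true <- vol$capAreas
  expect_equal(length(meas), length(true))
  expect_true(all(diff(order(meas)) == diff(order(true))))  # monotone
  expect_lte(max(abs(meas - true) / true), 0.15)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lte(abs(meas[i] / meas[j] - true[i] / true[j]) / (true[i] / true[j]),
               0.10)
})

test_that("dilation optimisation recovers a touching-cluster lower bound", {
  cell <- makeTestCell(8, soma = 3)
  vp <- noisefreeVP(seed = 2, vox = c(0.22, 0.082, 0.082))
  vp@cleftGap <- 0.02   # clusters effectively touching the soma
  vp@shellThickness <- 0.3
  vol <- synthVolume(cell, vp, minCapArea = 0.3)
  soma <- sphereFloodfill(vol$fill, threshold = 50)
  cl <- floodfillClusters(vol$marker, threshold = 50)
  d <- optimizeDilation(soma, cl, step = 0.082)
  expect_lte(as.numeric(d), 0.16 + 0.082 + 1e-9)
  ## empty clusters: warning and lower bound
  none <- new("ClusterSet", labels = array(0L, dim(cl@labels)),
              voxelCounts = integer(), thresholdUsed = 50,
              voxelSize = cl@voxelSize)
  expect_warning(d0 <- optimizeDilation(soma, none), "no clusters")
  expect_equal(as.numeric(d0), 0.16)
})

test_that("optimised dilation stays inside the documented range", {
  cell <- makeTestCell(c(15, 6), soma = 3.5)
  vol <- synthVolume(cell, noisefreeVP(seed = 11), minCapArea = 0.3)
  soma <- sphereFloodfill(vol$fill, threshold = 50)
  cl <- floodfillClusters(vol$marker, threshold = 50)
  d <- as.numeric(optimizeDilation(soma, cl, step = 0.123))
  expect_gte(d, 0.16)
  expect_lte(d, 0.76)
})
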