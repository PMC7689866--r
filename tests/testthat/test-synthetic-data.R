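test_that("cohort generation honours the noise-free limit", {
  p <- cohortParams(nCells = 5, seed = 3, ageRange = c(2, 2),
                    strongestIntercept = 8, strongestSDLog = 0,
                    sfScatterSDLog = 0, rorNoiseCV = c(0, 0))
  cells <- makeCohort(p)
  strongest <- vapply(cells, function(c) max(c@inputs$true_ror), numeric(1))
  expect_equal(strongest, rep(8, 5), tolerance = 1e-12)
})

test_that("mean input count per cell matches the developmental census", {
  cells <- makeCohort(cohortParams(nCells = 32, seed = 11))
  counts <- vapply(cells, function(c) nrow(c@inputs), integer(1))
  expect_gte(mean(counts), 4.6)   # 5.6 within 2 SE
  expect_lte(mean(counts), 6.6)
})

test_that("the power law inverts exactly", {
  expect_equal(areaFromRoR(6.8), 1.0, tolerance = 1e-12)
  ror <- c(0.9, 3.7, 19)
  expect_equal(6.8 * areaFromRoR(ror)^0.35, ror, tolerance = 1e-9)
})

test_that("noise-free cells satisfy the power law to machine precision", {
  p <- cohortParams(nCells = 6, seed = 9, sfScatterSDLog = 0)
  cells <- makeCohort(p)
  for (cell in cells)
    expect_equal(6.8 * cell@trueContactAreas^0.35, cell@inputs$true_ror,
                 tolerance = 1e-9)
})

test_that("cohort and trace generation are deterministic given the seed", {
  p <- cohortParams(nCells = 3, seed = 21)
  c1 <- makeCohort(p); c2 <- makeCohort(p)
  expect_identical(c1[[2]]@inputs, c2[[2]]@inputs)
  tr1 <- synthStimExperiment(c1[[1]], c(0.1, 0.3), sweepsPerLevel = 4, seed = 5)
  tr2 <- synthStimExperiment(c1[[1]], c(0.1, 0.3), sweepsPerLevel = 4, seed = 5)
  expect_identical(traceSamples(tr1), traceSamples(tr2))
  sp1 <- synthSpontActivity(c1[[1]], 1, seed = 8)
  sp2 <- synthSpontActivity(c1[[1]], 1, seed = 8)
  expect_identical(traceSamples(sp1), traceSamples(sp2))
})

test_that("stimulation recruits inputs only above their threshold", {
  cell <- makeTestCell(5, lats = 2, thresholds = 0.2)
  tr <- synthStimExperiment(cell, c(0.1, 0.3), sweepsPerLevel = 8, seed = 2)
  ev <- classifyEvoked(detectEPSPs(tr), tr)
  evoked <- ev[ev$evoked, ]
  expect_true(all(evoked$intensity_mA == 0.3))
  expect_gte(nrow(evoked), 6)
})

test_that("a cell with no inputs yields only noise", {
  cell <- new("CellGroundTruth", age = 3, inputs = data.frame(),
              trueContactAreas = numeric(), somaRadius = 4)
  tr <- synthStimExperiment(cell, c(0.1, 0.3), sweepsPerLevel = 5, seed = 4)
  ev <- detectEPSPs(tr)
  expect_equal(nrow(ev), 0)
})

test_that("ground-truth evoked events equal recruited inputs that fired", {
  cell <- makeTestCell(c(8, 3), lats = c(2, 5), thresholds = c(0.1, 0.3),
                       actP = 1)
  tr <- synthStimExperiment(cell, c(0.2, 0.4), sweepsPerLevel = 6, seed = 3)
  gt <- tr@metadata$groundTruth
  perSweep <- table(factor(gt$sweep, levels = 1:12))
  expect_true(all(perSweep[1:6] == 1))   # only input 1 recruited
  expect_true(all(perSweep[7:12] == 2))  # both recruited, p = 1
})

test_that("latency jitter is reproduced at the observed precision", {
  cell <- makeTestCell(8, lats = 2.5, thresholds = 0.1, latCV = 0.023)
  tr <- synthStimExperiment(cell, 0.3, sweepsPerLevel = 100, seed = 6)
  ev <- classifyEvoked(detectEPSPs(tr), tr)
  lat <- ev$latency_ms[ev$evoked]
  expect_gte(length(lat), 90)
  jitter <- sd(lat) / mean(lat)
  expect_gte(jitter, 0.015)
  expect_lte(jitter, 0.032)
})

test_that("spontaneous generation obeys degenerate inputs", {
  cell <- makeTestCell(c(6, 2))
  expect_equal(length(traceSamples(synthSpontActivity(cell, 0, seed = 1))), 0)
  tr <- synthSpontActivity(cell, 2, burstRate = 0, seed = 1)
  expect_equal(nrow(tr@metadata$groundTruth), 0)
  expect_equal(nrow(detectEPSPs(tr)), 0)
})

test_that("spontaneous rate-of-rise modes sit near the true input strengths", {
  cell <- makeTestCell(c(9, 3.5), lats = c(2, 5), trialCV = 0.12)
  tr <- synthSpontActivity(cell, 20, seed = 13)
  ev <- detectEPSPs(tr)
  expect_gte(nrow(ev), 50)
  d <- density(log(ev$ror))
  for (target in c(9, 3.5)) {
    sel <- abs(d$x - log(target)) < 0.35
    mode <- exp(d$x[sel][which.max(d$y[sel])])
    expect_lte(abs(mode - target) / target, 0.2)
  }
})

test_that("synthetic volumes carry exact analytic truth", {
  vp <- volumeParams(seed = 4, voxelSize = c(0.33, 0.123, 0.123),
                     psfSigma = c(0, 0, 0),
                     noiseModel = list(gaussian_sd = 0, poisson_scale = 0))
  cell <- makeTestCell(c(20, 10), soma = 4)
  vol <- synthVolume(cell, vp, minCapArea = 0.3)
  expect_s4_class(vol$truth, "ContactReport")
  expect_equal(vol$truth@largestArea, max(vol$capAreas))
  expect_equal(vol$truth@contactRatio,
               max(vol$capAreas) / sum(vol$capAreas), tolerance = 1e-12)
  ## marker caps disconnected under 26-connectivity in the label image
  lab <- bruteLabel3d(vol$labelArray > 0)
  expect_equal(max(lab), length(vol$capAreas))
  ## determinism
  vol2 <- synthVolume(cell, vp, minCapArea = 0.3)
  expect_identical(intensities(vol$marker), intensities(vol2$marker))
})

test_that("zero-input volumes have empty truth", {
  cell <- new("CellGroundTruth", age = 3, inputs = data.frame(),
              trueContactAreas = numeric(), somaRadius = 2.5)
  vp <- volumeParams(seed = 2, voxelSize = c(0.44, 0.164, 0.164))
  vol <- synthVolume(cell, vp)
  expect_equal(length(vol$capAreas), 0)
  expect_equal(vol$truth@totalContactArea, 0)
  expect_true(all(vol$labelArray == 0L))
})

test_that("two caps give the expected true contact ratio", {
  cell <- makeTestCell(c(6.8 * 10^0.35, 6.8 * 2^0.35), soma = 4)
  vp <- volumeParams(seed = 5, voxelSize = c(0.44, 0.164, 0.164),
                     psfSigma = c(0, 0, 0),
                     noiseModel = list(gaussian_sd = 0, poisson_scale = 0))
  vol <- synthVolume(cell, vp, minCapArea = 0.3)
  expect_equal(sort(vol$capAreas), c(2, 10), tolerance = 1e-9)
  expect_equal(vol$truth@contactRatio, 10 / 12, tolerance = 1e-9)
})
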