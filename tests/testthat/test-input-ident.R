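grp <- function(intensity, rors, lats, rate = 0.9, n = length(rors)) {
  list(intensity = intensity, rors = rors, latencies = lats,
       response_rate = rate, n_sweeps = n)
}

test_that("Welch's t matches hand computation and the reference", {
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(welchT(c(1, 2, 3), c(4, 5, 6)), 3.674, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.5)
    expect_equal(welchT(x, y), abs(unname(t.test(x, y)$statistic)),
                 tolerance = 1e-10)
  }
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("intensity grouping tabulates per-sweep responses", {
  cell <- makeTestCell(c(8, 2), lats = c(2, 5), thresholds = c(0.1, 0.25))
  tr <- synthStimExperiment(cell, c(0.15, 0.3), sweepsPerLevel = 10, seed = 2)
  ev <- classifyEvoked(detectEPSPs(tr), tr)
  gr <- groupByIntensity(ev, tr)
  expect_length(gr, 2)
  expect_equal(vapply(gr, `[[`, numeric(1), "intensity"), c(0.15, 0.3))
  expect_gte(gr[[1]]$response_rate, 0.9)
  ## empty event list -> groups with zero responses
  gr0 <- groupByIntensity(ev[0, ], tr)
  expect_true(all(vapply(gr0, function(g) g$response_rate, numeric(1)) == 0))
})

test_that("recruitment needs both the summed-t and the 20% increase", {
  set.seed(42)
  base <- grp(0.1, rnorm(30, 2, 0.3), rnorm(30, 5, 0.2))
  ## identical distributions: no new input beyond the first
  same <- grp(0.2, rnorm(30, 2, 0.3), rnorm(30, 5, 0.2))
  out <- scanRecruitment(list(base, same))
  expect_equal(nrow(out), 1)
  ## large summed t and a >20% increase: new input
  jump <- grp(0.2, rnorm(30, 9, 1), rnorm(30, 2, 0.2))
  out2 <- scanRecruitment(list(base, jump))
  expect_equal(nrow(out2), 2)
  ## large t but a <20% increase: rejected
  small <- grp(0.2, rnorm(30, 2.2, 0.05), rnorm(30, 5.8, 0.1))
  out3 <- scanRecruitment(list(base, small))
  expect_equal(nrow(out3), 1)
  expect_error(scanRecruitment(list(base)), "fewer than 2")
})

test_that("deconvolution subtracts same-latency known inputs", {
  g <- grp(0.3, rep(12, 20), rep(2.0, 20))
  none <- data.frame(mean_ror = numeric(), mean_latency = numeric())
  expect_equal(deconvolveRoR(g, none), 12)
  known <- data.frame(mean_ror = 4, mean_latency = 2.3)
  expect_equal(deconvolveRoR(g, known), 8)
  far <- data.frame(mean_ror = 4, mean_latency = 3.1)
  expect_equal(deconvolveRoR(g, far), 12)
  over <- data.frame(mean_ror = c(8, 7), mean_latency = c(2.0, 2.2))
  expect_warning(res <- deconvolveRoR(g, over), "degenerate")
  expect_true(is.na(res))
})

test_that("the spontaneous cross-check accepts and rejects as specified", {
  expect_true(as.logical(spontCrosscheck(8, c(2, 7.5, 30))))
  expect_false(as.logical(spontCrosscheck(8, c(1, 2, 4.9))))
  unchecked <- spontCrosscheck(8, numeric())
  expect_true(as.logical(unchecked))
  expect_false(attr(unchecked, "checked"))
})

test_that("cross-check prunes spurious candidates but keeps true inputs", {
  ## spurious candidates emulate the scan's failure modes: deconvolution
  ## overshoots and un-subtracted sums of two inputs
  cells <- makeCohort(cohortParams(nCells = 30, seed = 31))
  keptTrue <- 0; nTrue <- 0; keptSpur <- 0; nSpur <- 0
  for (i in seq_along(cells)) {
    tr <- synthSpontActivity(cells[[i]], 6, seed = 1000 + i)
    sp <- detectEPSPs(tr)$ror
    if (length(sp) < 30) next
    true <- cells[[i]]@inputs$true_ror
    for (cand in true[true >= 2]) {
      nTrue <- nTrue + 1
      if (as.logical(spontCrosscheck(cand, sp))) keptTrue <- keptTrue + 1
    }
    s1 <- max(true); s2 <- sort(true, TRUE)[2]
    for (cand in c(1.5 * s1, s1 + s2)) {
      if (any(abs(true - cand) <= 0.25 * cand)) next
      nSpur <- nSpur + 1
      if (as.logical(spontCrosscheck(cand, sp))) keptSpur <- keptSpur + 1
    }
  }
  expect_gte(nTrue, 20)
  expect_gte(keptTrue / nTrue, 0.9)
  expect_lte(keptSpur / nSpur, 0.2)
})

test_that("spontaneous peak analysis finds missed strong inputs", {
  ## evoked stimulation missed the 18 V/s input; spontaneous data has it
  cell <- makeTestCell(c(18, 3), lats = c(2, 5), trialCV = 0.1)
  tr <- synthSpontActivity(cell, 15, seed = 8)
  sp <- detectEPSPs(tr)$ror
  evoked <- data.frame(mean_ror = 3.1, ror_sd = 0.4, mean_latency = 5,
                       recruit_intensity = 0.2, n = 20, source = "evoked")
  out <- spontPeakInputs(sp, evoked)
  expect_gte(nrow(out), 1)
  expect_lte(abs(out$mean_ror[1] - 18) / 18, 0.2)
  ## unimodal weak distribution: at most one small input
  set.seed(12)
  weak <- exp(runif(200, log(0.7), log(2)))
  outW <- spontPeakInputs(weak, NULL)
  expect_lte(sum(outW$mean_ror < 2.5), 1)
  ## too few events: empty with a warning
  expect_warning(out0 <- spontPeakInputs(rnorm(5, 3)), "too few")
  expect_equal(nrow(out0), 0)
})

test_that("cell assembly sorts, flags and computes the competition index", {
  ev <- data.frame(mean_ror = c(19, 3.7), ror_sd = c(2, 0.5),
                   mean_latency = c(2.1, 4.5), recruit_intensity = c(0.2, 0.3),
                   n = c(30, 25), source = "evoked")
  cell <- assembleCell(ev, NULL, age = 5)
  expect_s4_class(cell, "CellInputs")
  expect_equal(competitionIndex(cell), 3.7 / 19, tolerance = 1e-12)
  inp <- inputEstimates(cell)
  expect_equal(inp$strong, c(TRUE, FALSE))
  ## strong threshold is strict at 10 V/s
  one <- function(r) assembleCell(
    data.frame(mean_ror = r, ror_sd = 1, mean_latency = 2,
               recruit_intensity = 0.2, n = 10, source = "evoked"))
  expect_true(inputEstimates(one(10.5))$strong)
  expect_false(inputEstimates(one(9.5))$strong)
  ## equal strongest inputs give competition index 1
  eq <- data.frame(mean_ror = c(8, 8), ror_sd = 1, mean_latency = c(2, 5),
                   recruit_intensity = 0.2, n = 10, source = "evoked")
  expect_equal(competitionIndex(assembleCell(eq)), 1.0)
  ## duplicates merge with evoked provenance preferred
  sp <- data.frame(mean_ror = 18.2, ror_sd = 2, mean_latency = NA,
                   recruit_intensity = NA, n = 40, source = "spontaneous")
  dedup <- assembleCell(ev, sp, age = 5)
  expect_equal(nrow(inputEstimates(dedup)), 2)
  expect_equal(inputEstimates(dedup)$source[1], "evoked")
  expect_error(assembleCell(ev[0, ], NULL), "no inputs")
})

test_that("end-to-end identification recovers a simple cell", {
  cell <- makeTestCell(c(16, 3.7, 1.3), lats = c(2, 4.8, 6),
                       thresholds = c(0.28, 0.12, 0.2),
                       actP = 0.9, trialCV = 0.1, latCV = 0.02)
  stim <- synthStimExperiment(cell, seq(0.05, 0.45, by = 0.05),
                              sweepsPerLevel = 30, seed = 5)
  spont <- synthSpontActivity(cell, 8, seed = 6)
  res <- identifyInputs(stim, spont, age = 5)
  inp <- inputEstimates(res)
  expect_lte(abs(inp$mean_ror[1] - 16) / 16, 0.15)
  expect_lte(abs(inp$mean_ror[2] - 3.7), 1.0)
  expect_true(inp$strong[1])
  expect_gte(competitionIndex(res), 0.1)
  expect_lte(competitionIndex(res), 0.45)
})

test_that("competition index lies in (0, 1] across identified cells", {
  out <- runCohortPhysiology(cohortParams(nCells = 8, seed = 77))
  ci <- out$results$competition_index
  ci <- ci[!is.na(ci)]
  expect_gte(length(ci), 5)
  expect_true(all(ci > 0 & ci <= 1))
})
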