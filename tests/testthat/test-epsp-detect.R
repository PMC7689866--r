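mkTrace <- function(v, fs = 25000, stim = NULL, rest = -70) {
  if (is.null(stim)) stim <- data.frame(time_s = numeric(),
                                        intensity_mA = numeric())
  new("TraceRecording", samples = v, samplingRate = fs, stimuli = stim,
      restingPotential = rest, metadata = list())
}

test_that("a flat noisy trace yields zero events", {
  set.seed(1)
  v <- -70 + rnorm(25000 * 2, 0, 0.1)  # 0.1 mV RMS white noise
  expect_equal(nrow(detectEPSPs(mkTrace(v))), 0)
})

test_that("a clean kernel event is measured within 2% of its rate of rise", {
  cell <- makeTestCell(5, lats = 2, thresholds = 0.1)
  tr <- synthStimExperiment(cell, 0.3, sweepsPerLevel = 3, seed = 1,
                            noiseSd = 0)
  ev <- detectEPSPs(tr)
  expect_equal(nrow(ev), 3)
  expect_lte(max(abs(ev$ror - 5) / 5), 0.02)
})

test_that("sub-threshold events are discarded", {
  cell <- makeTestCell(0.6, lats = 2, thresholds = 0.1)
  tr <- synthStimExperiment(cell, 0.3, sweepsPerLevel = 5, seed = 1,
                            noiseSd = 0)
  expect_equal(nrow(detectEPSPs(tr)), 0)
  ## and just above threshold it is kept
  cell2 <- makeTestCell(1.0, lats = 2, thresholds = 0.1)
  tr2 <- synthStimExperiment(cell2, 0.3, sweepsPerLevel = 5, seed = 1,
                             noiseSd = 0)
  expect_equal(nrow(detectEPSPs(tr2)), 5)
})

test_that("noise-free detection recovers every ground-truth event", {
  cell <- makeTestCell(c(7, 2.5), lats = c(2, 5), thresholds = c(0.1, 0.1))
  tr <- synthStimExperiment(cell, 0.3, sweepsPerLevel = 10, seed = 2,
                            noiseSd = 0)
  ev <- detectEPSPs(tr)
  gt <- tr@metadata$groundTruth
  expect_equal(nrow(ev), nrow(gt))  # recall = precision = 1
  expect_true(all(diff(ev$onset_s) > 0))
})

test_that("evoked classification follows the 1-8 ms window", {
  stim <- data.frame(time_s = 0.1, intensity_mA = 0.2)
  ev <- data.frame(onset_s = 0.1 + c(0.0005, 0.0021, 0.009),
                   ror = c(5, 5, 5), amplitude_mV = 1, latency_ms = NA,
                   evoked = FALSE, intensity_mA = NA, prespike = FALSE,
                   prespike_amp = NA, triggered_ap = FALSE)
  tr <- mkTrace(rep(-70, 25000 * 0.2), stim = stim)
  out <- classifyEvoked(ev, tr)
  expect_equal(out$evoked, c(FALSE, TRUE, FALSE))
  expect_equal(out$latency_ms[2], 2.1, tolerance = 1e-9)
  expect_equal(out$intensity_mA[2], 0.2)
})

test_that("AP detection counts inserted spikes and flags antidromic ones", {
  expect_equal(nrow(detectAPs(mkTrace(rep(-70, 50000)))), 0)
  ## strong input fires an AP on every sweep
  cell <- makeTestCell(40, lats = 2, thresholds = 0.1)
  tr <- synthStimExperiment(cell, 0.3, sweepsPerLevel = 3, seed = 3)
  aps <- detectAPs(tr)
  expect_equal(nrow(aps), 3)
  expect_equal(length(tr@metadata$apTimes), 3)
  expect_true(all(!aps$antidromic))
  ## an AP 0.8 ms after the stimulus is flagged antidromic
  fs <- 25000
  v <- rep(-70, 5000)
  ap <- 85 * exp(-(seq(0, 3, by = 1000 / fs) - 0.4)^2 / (2 * 0.15^2))
  i0 <- round(0.05 * fs) + round(0.0008 * fs)
  v[i0:(i0 + length(ap) - 1)] <- v[i0:(i0 + length(ap) - 1)] + ap
  tra <- mkTrace(v, stim = data.frame(time_s = 0.05, intensity_mA = 0.35))
  apsA <- detectAPs(tra)
  expect_equal(nrow(apsA), 1)
  expect_true(apsA$antidromic[1])
})

test_that("prespikes are detected with faithful amplitudes", {
  cell <- makeTestCell(25, lats = 2, thresholds = 0.1, calyceal = TRUE,
                       preAmp = 0.30)
  tr <- synthStimExperiment(cell, 0.3, sweepsPerLevel = 20, seed = 4,
                            noiseSd = 0.03)
  ev <- classifyEvoked(detectEPSPs(tr), tr)
  ev <- detectPrespikes(tr, ev)
  big <- ev[ev$evoked & ev$ror > 10, ]
  expect_gte(mean(big$prespike), 0.5)
  m <- mean(big$prespike_amp, na.rm = TRUE)
  expect_lte(abs(m - 0.30) / 0.30, 0.2)
})

test_that("events without an inserted prespike stay unflagged", {
  cell <- makeTestCell(25, lats = 2, thresholds = 0.1, calyceal = FALSE)
  tr <- synthStimExperiment(cell, 0.3, sweepsPerLevel = 20, seed = 5,
                            noiseSd = 0.03)
  ev <- classifyEvoked(detectEPSPs(tr), tr)
  ev <- detectPrespikes(tr, ev)
  big <- ev[ev$evoked & ev$ror > 10, ]
  expect_lte(mean(big$prespike), 0.2)
})

test_that("P_AP is the fraction of EPSPs followed by an AP", {
  ev <- data.frame(onset_s = seq(0.1, 1.2, length.out = 12))
  aps <- ev$onset_s[1:8] + 0.0012
  expect_equal(computePAP(ev, aps), 8 / 12, tolerance = 1e-12)
  expect_equal(computePAP(ev, ev$onset_s + 0.001), 1.0)
  expect_equal(computePAP(ev, numeric()), 0.0)
  expect_error(computePAP(ev[0, ], aps), "zero events")
})

test_that("retained events always exceed the minimal rate of rise", {
  cell <- makeTestCell(c(6, 1.2), lats = c(2, 5), thresholds = c(0.1, 0.2),
                       actP = 0.8, trialCV = 0.3)
  for (s in 1:3) {
    tr <- synthStimExperiment(cell, c(0.15, 0.3), sweepsPerLevel = 10, seed = s)
    ev <- detectEPSPs(tr)
    expect_true(all(ev$ror > 0.7))
    expect_true(all(diff(ev$onset_s) * 1000 >= 0.6 - 1e-9))
  }
})

test_that("low sampling rates are rejected for derivative smoothing", {
  tr <- mkTrace(rep(-70, 1000), fs = 5000)
  expect_error(detectEPSPs(tr), "sampling rate too low")
})
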