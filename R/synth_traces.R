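#' @include AllClasses.R utils.R
NULL

## ------------------------------------------------------------------
## EPSP kernel
## ------------------------------------------------------------------

## Unit difference-of-exponentials EPSP kernel sampled at fs, starting at the
## kernel onset. Returned without amplitude scaling.
epspKernelUnit <- function(fs, tauRise = 0.4, tauDecay = 3, durMs = 18) {
  t <- seq(0, durMs, by = 1000 / fs)
  exp(-t / tauDecay) - exp(-t / tauRise)
}

## The kernel has a derivative kink at onset, so its analytic peak slope is
## not what a Savitzky-Golay-smoothed slope measurement returns. We calibrate
## the amplitude numerically: the scale factor is the smoothed-slope maximum
## of the clean sampled unit kernel, so that generator truth and detector
## measurement share one operational rate-of-rise definition.
.kernelCache <- new.env(parent = emptyenv())

kernelRorScale <- function(fs, tauRise = 0.4, tauDecay = 3) {
  key <- paste(fs, tauRise, tauDecay, sep = "_")
  if (!is.null(.kernelCache[[key]])) return(.kernelCache[[key]])
  w <- epspKernelUnit(fs, tauRise, tauDecay)
  pad <- rep(0, 50)
  d1 <- sgDerivative(c(pad, w, pad), fs, m = 1L)
  sc <- max(d1)  # V/s per unit kernel amplitude (kernel in mV)
  .kernelCache[[key]] <- sc
  sc
}

## Scaled kernel whose measured (smoothed) max slope equals `ror` V/s.
epspKernel <- function(ror, fs, tauRise = 0.4, tauDecay = 3, durMs = 18) {
  epspKernelUnit(fs, tauRise, tauDecay, durMs) *
    (ror / kernelRorScale(fs, tauRise, tauDecay))
}

## Biphasic prespike: derivative of a Gaussian, total width ~0.5 ms,
## normalised to a requested peak-to-peak amplitude (mV).
prespikeKernel <- function(p2p, fs, widthMs = 0.5) {
  s <- widthMs / 4
  t <- seq(-widthMs, widthMs, by = 1000 / fs)
  w <- -t * exp(-t^2 / (2 * s^2))
  w * (p2p / diff(range(w)))
}

## Stereotyped AP waveform added when the subthreshold sum crosses threshold.
## Smooth at onset (no step at insertion) and with an AHP whose recovery
## slope stays below the EPSP detection floor.
apKernel <- function(fs, amp = 82, peakMs = 0.45, sigmaMs = 0.14, ahp = -2.5) {
  t <- seq(0, 24, by = 1000 / fs)
  spike <- amp * exp(-(t - peakMs)^2 / (2 * sigmaMs^2))
  u <- pmax(0, t - 0.7)
  rec <- ahp * (1 - exp(-u / 0.25)) * exp(-u / 4)
  spike + rec
}

## Brief biphasic stimulus artefact.
stimArtefact <- function(fs, amp = 3) {
  n <- max(2L, round(0.12e-3 * fs))
  amp * c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2)))
}

## FFT convolution of an impulse train with a causal kernel (kernel onset at
## the impulse sample); returns the first length(imp) samples.
.convTrain <- function(imp, kern) {
  n <- length(imp)
  m <- stats::nextn(n + length(kern), c(2, 3, 5))
  full <- Re(fft(fft(c(imp, numeric(m - n))) *
                   fft(c(kern, numeric(m - length(kern)))),
                 inverse = TRUE)) / m
  full[seq_len(n)]
}


## Smooth (band-limited) membrane noise: white Gaussian low-passed with a
## Gaussian kernel of sigma `tauMs`, rescaled to sd `sdmV`.
membraneNoise <- function(n, sdmV, fs, tauMs = 0.4) {
  if (n == 0 || sdmV <= 0) return(rep(0, n))
  s <- tauMs * fs / 1000
  r <- ceiling(3 * s)
  k <- exp(-(seq(-r, r))^2 / (2 * s^2))
  k <- k / sqrt(sum(k^2))   # unit noise gain
  x <- rnorm(n + 2 * r)
  y <- .convTrain(x, k)
  y[(2 * r + 1):(n + 2 * r)] * sdmV
}

## ------------------------------------------------------------------
## Shared trace assembly
## ------------------------------------------------------------------

## events: data.frame(time_s, ror, input, prespike_amp); stimuli: data.frame
## (time_s, intensity_mA). Returns a TraceRecording with ground truth attached.
.assembleTrace <- function(cell, events, nSamples, fs, stimuli, noiseSd,
                           noiseTauMs, apThreshold, rest, meta = list()) {
  v <- rep(0, nSamples)
  addTrain <- function(starts, weights, kern) {
    ## sparse in-place accumulation (cheaper than FFT for event trains)
    lk <- length(kern)
    for (q in seq_along(starts)) {
      s <- starts[q]
      if (s > nSamples || s < 1) next
      e <- min(nSamples, s + lk - 1L)
      v[s:e] <<- v[s:e] + kern[seq_len(e - s + 1L)] * weights[q]
    }
  }
  if (nrow(events)) {
    events <- events[order(events$time_s), , drop = FALSE]
    starts <- as.integer(round(events$time_s * fs)) + 1L
    addTrain(starts, events$ror, epspKernel(1, fs))
    pre <- which(!is.na(events$prespike_amp) & events$prespike_amp > 0)
    if (length(pre)) {
      pk <- prespikeKernel(1, fs)
      poff <- as.integer(round(0.45e-3 * fs)) + length(pk) %/% 2L
      addTrain(starts[pre] - poff, events$prespike_amp[pre], pk)
    }
  }
  ## postsynaptic APs whenever the summed depolarisation crosses threshold
  ## (crossings evaluated on the subthreshold sum, with a refractory period)
  apTimes <- numeric()
  depol <- rest + v
  thrCross <- which(depol[-1] >= apThreshold & depol[-length(depol)] < apThreshold)
  if (length(thrCross)) {
    refr <- as.integer(round(3e-3 * fs))
    keep <- logical(length(thrCross))
    last <- -refr
    for (q in seq_along(thrCross)) {
      if (thrCross[q] - last >= refr) { keep[q] <- TRUE; last <- thrCross[q] }
    }
    apStarts <- thrCross[keep]
    addTrain(apStarts, rep(1, length(apStarts)), apKernel(fs))
    apTimes <- apStarts / fs
  }
  if (nrow(stimuli)) {
    idx <- pmin(nSamples, as.integer(round(stimuli$time_s * fs)) + 1L)
    addTrain(idx, rep(1, length(idx)), stimArtefact(fs))
  }
  v <- v + rest + membraneNoise(nSamples, noiseSd, fs, noiseTauMs)
  meta$groundTruth <- events
  meta$apTimes <- apTimes
  new("TraceRecording", samples = v, samplingRate = fs, stimuli = stimuli,
      restingPotential = rest, metadata = meta)
}

## ------------------------------------------------------------------
## Evoked protocol
## ------------------------------------------------------------------

#' Simulate an afferent-stimulation experiment
#'
#' For each stimulation intensity, `sweepsPerLevel` sweeps are generated
#' (concatenated into one trace, one stimulus per sweep). Every input whose
#' recruitment threshold is at or below the intensity fires with its
#' activation probability, at a normally jittered latency, contributing a
#' difference-of-exponentials EPSP with per-trial lognormal rate-of-rise
#' noise. A stereotyped postsynaptic AP is inserted when the summed
#' depolarisation crosses `apThreshold`; a calyceal input contributes a
#' biphasic prespike before its EPSP. Stimulus artefacts mark each stimulus.
#'
#' @param cell a [CellGroundTruth-class] object.
#' @param intensities stimulation intensities, mA, sorted ascending.
#' @param sweepsPerLevel sweeps per intensity (the reference protocol
#'   collected >30 per level).
#' @param seed integer seed.
#' @param sweepMs sweep window length, ms.
#' @param stimOffsetMs stimulus time within each sweep, ms.
#' @param noiseSd membrane noise SD, mV.
#' @param noiseTauMs noise correlation time (Gaussian low-pass sigma), ms.
#' @param apThreshold AP firing threshold, mV.
#' @param rest resting potential, mV.
#' @param fs sampling rate, Hz.
#' @return a [TraceRecording-class]; `metadata(trace)$groundTruth` lists every
#'   inserted event (sweep, input index, onset, rate of rise, intensity).
#' @export
synthStimExperiment <- function(cell, intensities, sweepsPerLevel = 30L,
                                seed = 1L, sweepMs = 16, stimOffsetMs = 2,
                                noiseSd = 0.05, noiseTauMs = 0.4,
                                apThreshold = -60, rest = -70, fs = 25000) {
  stopifnot1(is(cell, "CellGroundTruth"), "cell must be a CellGroundTruth")
  stopifnot1(length(intensities) >= 1, "empty intensity protocol")
  stopifnot1(!is.unsorted(intensities, strictly = TRUE),
             "intensities must be sorted ascending")
  stopifnot1(sweepsPerLevel >= 1, "sweepsPerLevel must be >= 1")

  sweepLen <- as.integer(round(sweepMs * fs / 1000))
  nSweeps <- length(intensities) * sweepsPerLevel
  n <- sweepLen * nSweeps
  inp <- cell@inputs

  withSeed(seed, {
    stim <- data.frame(
      time_s = (seq_len(nSweeps) - 1L) * sweepLen / fs + stimOffsetMs / 1000,
      intensity_mA = rep(intensities, each = sweepsPerLevel))
    ev <- list()
    if (nrow(inp)) {
      for (j in seq_len(nrow(inp))) {
        active <- stim$intensity_mA >= inp$recruitment_threshold[j]
        fired <- active & (runif(nSweeps) < inp$activation_prob[j])
        k <- which(fired)
        if (!length(k)) next
        lat <- rnorm(length(k), inp$latency_mean[j],
                     inp$latency_cv[j] * inp$latency_mean[j])
        lat <- pmax(0.8, lat)
        cv <- inp$ror_trial_cv[j]
        ror <- inp$true_ror[j] * exp(rnorm(length(k), 0, cv) - cv^2 / 2)
        ev[[length(ev) + 1L]] <- data.frame(
          sweep = k, input = j,
          time_s = stim$time_s[k] + lat / 1000,
          ror = ror, latency_ms = lat,
          intensity_mA = stim$intensity_mA[k],
          prespike_amp = if (inp$is_calyceal[j]) inp$prespike_amp[j] else 0)
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(sweep = integer(), input = integer(), time_s = numeric(),
                 ror = numeric(), latency_ms = numeric(),
                 intensity_mA = numeric(), prespike_amp = numeric())
    .assembleTrace(cell, events, n, fs, stim, noiseSd, noiseTauMs,
                   apThreshold, rest,
                   meta = list(seed = seed, sweepLength_s = sweepLen / fs,
                               sweepsPerLevel = sweepsPerLevel,
                               stimOffset_s = stimOffsetMs / 1000,
                               protocol = "stimulation"))
  })
}

## ------------------------------------------------------------------
## Spontaneous activity
## ------------------------------------------------------------------

#' Simulate spontaneous burst activity
#'
#' Bursts arrive as a Poisson process; within a burst each input emits events
#' as an independent Poisson process at `withinBurstRate`, with the same
#' per-trial rate-of-rise jitter and prespike/AP mechanics as the evoked
#' generator. The inserted-event table is attached as ground truth.
#'
#' @param cell a [CellGroundTruth-class] object.
#' @param duration recording duration, s.
#' @param burstRate burst rate, Hz.
#' @param withinBurstRate per-input event rate inside a burst, Hz.
#' @param seed integer seed.
#' @param burstDur mean burst duration, s (exponentially distributed).
#' @inheritParams synthStimExperiment
#' @return a [TraceRecording-class] without stimuli.
#' @export
synthSpontActivity <- function(cell, duration, burstRate = 0.5,
                               withinBurstRate = 40, seed = 1L,
                               burstDur = 0.6, noiseSd = 0.05,
                               noiseTauMs = 0.4, apThreshold = -60,
                               rest = -70, fs = 25000) {
  stopifnot1(is(cell, "CellGroundTruth"), "cell must be a CellGroundTruth")
  stopifnot1(duration >= 0, "duration must be >= 0")
  n <- as.integer(round(duration * fs))
  inp <- cell@inputs
  emptyStim <- data.frame(time_s = numeric(), intensity_mA = numeric())

  withSeed(seed, {
    ev <- list()
    if (n > 0 && burstRate > 0 && nrow(inp)) {
      nBursts <- rpois(1, burstRate * duration)
      starts <- sort(runif(nBursts, 0, duration))
      lens <- stats::rexp(nBursts, 1 / burstDur)
      for (b in seq_len(nBursts)) {
        bEnd <- min(duration - 0.02, starts[b] + lens[b])
        if (bEnd <= starts[b]) next
        for (j in seq_len(nrow(inp))) {
          nev <- rpois(1, withinBurstRate * (bEnd - starts[b]))
          if (!nev) next
          tt <- sort(runif(nev, starts[b], bEnd))
          cv <- inp$ror_trial_cv[j]
          ror <- inp$true_ror[j] * exp(rnorm(nev, 0, cv) - cv^2 / 2)
          ev[[length(ev) + 1L]] <- data.frame(
            sweep = NA_integer_, input = j, time_s = tt, ror = ror,
            latency_ms = NA_real_, intensity_mA = NA_real_,
            prespike_amp = if (inp$is_calyceal[j]) inp$prespike_amp[j] else 0)
        }
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(sweep = integer(), input = integer(), time_s = numeric(),
                 ror = numeric(), latency_ms = numeric(),
                 intensity_mA = numeric(), prespike_amp = numeric())
    .assembleTrace(cell, events, n, fs, emptyStim, noiseSd, noiseTauMs,
                   apThreshold, rest,
                   meta = list(seed = seed, protocol = "spontaneous",
                               burstRate = burstRate,
                               withinBurstRate = withinBurstRate))
  })
}
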