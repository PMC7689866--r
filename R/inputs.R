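#' @include AllClasses.R utils.R detect.R
NULL

#' Group evoked responses by stimulation intensity
#'
#' Builds one group per distinct stimulus intensity. The per-sweep evoked
#' response is summarised by the steepest evoked event of that sweep (its rate
#' of rise and latency), optionally restricted to a latency domain; the
#' response rate is the fraction of sweeps at that intensity with at least one
#' evoked event.
#'
#' @param events classified event table (see [classifyEvoked()]).
#' @param trace the stimulation [TraceRecording-class] (provides the sweep
#'   roster per intensity).
#' @param latencyDomain optional numeric length-2: only events with latency in
#'   `(lo, hi]` ms are considered.
#' @return list of groups, each a list with `intensity`, `rors`, `latencies`,
#'   `response_rate`, `n_sweeps`; sorted by ascending intensity.
#' @export
groupByIntensity <- function(events, trace, latencyDomain = NULL) {
  st <- trace@stimuli
  stopifnot1(nrow(st) > 0, "trace carries no stimuli")
  ev <- events[events$evoked & !is.na(events$intensity_mA), , drop = FALSE]
  if (!is.null(latencyDomain))
    ev <- ev[ev$latency_ms > latencyDomain[1] & ev$latency_ms <= latencyDomain[2], ,
             drop = FALSE]
  intensities <- sort(unique(st$intensity_mA))
  sweepOf <- findInterval(ev$onset_s, st$time_s)
  out <- list()
  for (I in intensities) {
    sweeps <- which(st$intensity_mA == I)
    sel <- which(sweepOf %in% sweeps)
    if (!length(sel) && !nrow(ev)) { }
    rors <- lats <- numeric()
    if (length(sel)) {
      bySweep <- split(sel, sweepOf[sel])
      pick <- vapply(bySweep, function(ix) ix[which.max(ev$ror[ix])], integer(1))
      rors <- ev$ror[pick]
      lats <- ev$latency_ms[pick]
    }
    out[[length(out) + 1L]] <- list(
      intensity = I, rors = as.numeric(rors), latencies = as.numeric(lats),
      response_rate = length(rors) / length(sweeps),
      n_sweeps = length(sweeps))
  }
  out[vapply(out, function(g) g$n_sweeps > 0, TRUE)]
}

#' Welch's t statistic (absolute value)
#'
#' `|t| = |mean(x) - mean(y)| / sqrt(var(x)/nx + var(y)/ny)`; the absolute
#' value feeds the summed recruitment criterion. Degenerate zero-variance
#' pairs of identical samples give 0.
#'
#' @param x,y numeric samples, each with at least 2 values.
#' @return the absolute Welch t.
#' @export
#' @examples
#' welchT(c(1, 2, 3), c(4, 5, 6))  # 3.674
welchT <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welchT needs at least 2 values per sample", call. = FALSE)
  se2 <- var(x) / length(x) + var(y) / length(y)
  num <- mean(x) - mean(y)
  if (se2 == 0) return(if (num == 0) 0 else Inf)
  abs(num) / sqrt(se2)
}

#' Scan consecutive intensity groups for input recruitment
#'
#' For each consecutive pair of responsive groups, Welch's t is computed for
#' the response latency and rate of rise and the absolute values summed. A
#' transition recruits a new input iff the summed t exceeds `tSumThreshold`
#' (default 6) and the mean response rate of rise increases by more than
#' `minIncrease` (default 20%). Transitions whose response rate jumps by more
#' than `probShiftRateJump` while the latency component stays below
#' `probShiftLatT` are classified as activation-probability shifts of
#' existing inputs, not new inputs. The first responsive group spawns the
#' first input; later candidates are strength-deconvolved against
#' already-identified inputs of similar latency via [deconvolveRoR()].
#'
#' @param groups output of [groupByIntensity()] (at least 2 groups).
#' @param tSumThreshold threshold on `|t_latency| + |t_ror|`.
#' @param minIncrease required relative increase of the mean rate of rise.
#' @param latencyTol latency tolerance for deconvolution, ms.
#' @param probShiftRateJump,probShiftLatT probability-shift classification
#'   parameters (rate jump in fraction of sweeps; latency-t bound).
#' @param minRate,minEvents a group must reach this response rate and event
#'   count to participate.
#' @return data.frame of candidate inputs: `mean_ror`, `ror_sd`,
#'   `mean_latency`, `recruit_intensity`, `n`, `source`.
#' @export
scanRecruitment <- function(groups, tSumThreshold = 6, minIncrease = 0.20,
                            latencyTol = 0.5, probShiftRateJump = 0.20,
                            probShiftLatT = 2, minRate = 0.15, minEvents = 3L) {
  if (length(groups) < 2) stop("cannot scan: fewer than 2 intensity groups",
                               call. = FALSE)
  resp <- Filter(function(g) g$response_rate >= minRate &&
                   length(g$rors) >= minEvents, groups)
  cand <- data.frame(mean_ror = numeric(), ror_sd = numeric(),
                     mean_latency = numeric(), recruit_intensity = numeric(),
                     n = integer(), source = character())
  if (!length(resp)) return(cand)
  g1 <- resp[[1]]
  cand[1, ] <- list(mean(g1$rors), sd(g1$rors), mean(g1$latencies),
                    g1$intensity, length(g1$rors), "evoked")
  if (length(resp) == 1) return(cand)
  for (k in 2:length(resp)) {
    prev <- resp[[k - 1]]; cur <- resp[[k]]
    tLat <- welchT(prev$latencies, cur$latencies)
    tRor <- welchT(prev$rors, cur$rors)
    inc <- (mean(cur$rors) - mean(prev$rors)) / mean(prev$rors)
    rateJump <- cur$response_rate - prev$response_rate
    probShift <- rateJump > probShiftRateJump && tLat < probShiftLatT
    if (tLat + tRor > tSumThreshold && inc > minIncrease && !probShift) {
      ## the new input fires with probability < 1, so the new group mixes
      ## sweeps with and without it; estimate from the responses that exceed
      ## the previous group's distribution (the sweeps where it fired)
      split <- max(quantile(prev$rors, 0.95),
                   mean(prev$rors) + 2 * sd(prev$rors))
      up <- cur$rors > split
      newGrp <- if (sum(up) >= 4 && mean(up) > 0.2)
        list(rors = cur$rors[up], latencies = cur$latencies[up]) else cur
      newRor <- deconvolveRoR(newGrp, cand, latencyTol)
      if (!is.na(newRor))
        cand[nrow(cand) + 1L, ] <- list(newRor, sd(newGrp$rors),
                                        mean(newGrp$latencies), cur$intensity,
                                        length(newGrp$rors), "evoked")
    }
  }
  cand
}

#' Deconvolve a newly recruited input's rate of rise
#'
#' The candidate rate of rise is the new group's mean response rate of rise
#' minus the summed mean rates of rise of previously identified inputs whose
#' mean latency lies within `latencyTol` of the new group's mean latency
#' (their EPSPs merge with the new one). Non-positive results are floored at
#' zero with a warning and the candidate dropped (returned as NA).
#'
#' @param newGroup one group from [groupByIntensity()].
#' @param knownInputs data.frame with `mean_ror`, `mean_latency`.
#' @param latencyTol ms.
#' @return candidate rate of rise, V/s, or NA for a degenerate candidate.
#' @export
deconvolveRoR <- function(newGroup, knownInputs, latencyTol = 0.5) {
  gm <- mean(newGroup$rors)
  gl <- mean(newGroup$latencies)
  if (is.null(knownInputs) || !nrow(knownInputs)) return(gm)
  overlap <- !is.na(knownInputs$mean_latency) &
    abs(knownInputs$mean_latency - gl) <= latencyTol
  val <- gm - sum(knownInputs$mean_ror[overlap])
  if (val <= 0) {
    warning("degenerate candidate: overlapping known inputs exceed the group mean",
            call. = FALSE)
    return(NA_real_)
  }
  val
}

#' Cross-check a candidate input against spontaneous activity
#'
#' A candidate identified from stimulation is only accepted if spontaneous
#' EPSPs of similar rate of rise (within `relTol`) were recorded. For rich
#' spontaneous data the comparison is made against the rate-of-rise
#' *distribution*, as in the source analysis: the candidate must sit within
#' `relTol` of a density mode of the spontaneous rates of rise, or at least
#' `minFrac` of the spontaneous events must fall within `relTol` of it.
#' (A lone coincidental event in a long recording is not evidence, and
#' conversely a deconvolution overshoot landing in the upper tail of a
#' strong input's trial distribution must not pass.) With fewer than 20
#' spontaneous events a single matching event suffices; with none the
#' candidate is accepted but flagged unchecked.
#'
#' @param candidateRor candidate rate of rise, V/s.
#' @param spontRors rates of rise of detected spontaneous EPSPs.
#' @param relTol relative tolerance.
#' @param minFrac minimum matching fraction of the spontaneous events.
#' @return logical; attribute `checked` reports whether spontaneous data were
#'   available.
#' @export
spontCrosscheck <- function(candidateRor, spontRors, relTol = 0.20,
                            minFrac = 0.08) {
  if (!length(spontRors))
    return(structure(TRUE, checked = FALSE))
  if (length(spontRors) < 20) {
    ok <- any(abs(spontRors - candidateRor) <= relTol * candidateRor)
    return(structure(ok, checked = TRUE))
  }
  d <- density(log(spontRors), bw = "nrd0", adjust = 0.6)
  pp <- .peakProminence(d$y)
  pk <- pp$peaks[pp$prominence >= 0.02 * max(d$y)]
  ok <- any(abs(d$x[pk] - log(candidateRor)) <= log(1 + relTol)) ||
    mean(abs(spontRors - candidateRor) <= relTol * candidateRor) >= minFrac
  structure(ok, checked = TRUE)
}

## peak prominences on a density grid
.peakProminence <- function(y) {
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  prom <- vapply(peaks, function(p) {
    lhs <- y[seq_len(p)]
    rhs <- y[p:n]
    higherL <- which(lhs > y[p])
    higherR <- which(rhs > y[p]) + p - 1L
    floorL <- if (length(higherL)) min(y[max(higherL):p]) else min(lhs)
    floorR <- if (length(higherR)) min(y[p:min(higherR)]) else min(rhs)
    y[p] - max(floorL, floorR)
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Identify inputs from the spontaneous rate-of-rise distribution
#'
#' A kernel-density estimate (Silverman bandwidth) of the log-transformed
#' spontaneous rates of rise is searched for local maxima with prominence of
#' at least `promFrac` of the density maximum. Each retained mode becomes an
#' input (its strength the mean of events within `window` of the mode) unless
#' it matches an already-identified evoked input within `matchTol`; in
#' particular a spontaneous mode exceeding every evoked input (a strongest
#' input that stimulation failed to activate) is promoted.
#'
#' @param spontRors rates of rise of detected spontaneous EPSPs, V/s.
#' @param evokedInputs optional data.frame with `mean_ror` of evoked inputs.
#' @param minEvents minimum number of spontaneous events (default 20).
#' @param promFrac prominence threshold as a fraction of the density maximum.
#' @param matchTol relative tolerance for "already identified".
#' @param window relative half-width for mode strength estimation.
#' @return data.frame of spontaneous inputs (`mean_ror`, `ror_sd`,
#'   `mean_latency` = NA, `n`, `source` = "spontaneous").
#' @export
spontPeakInputs <- function(spontRors, evokedInputs = NULL, minEvents = 20L,
                            promFrac = 0.05, matchTol = 0.20, window = 0.25) {
  out <- data.frame(mean_ror = numeric(), ror_sd = numeric(),
                    mean_latency = numeric(), recruit_intensity = numeric(),
                    n = integer(), source = character())
  if (length(spontRors) < minEvents) {
    warning("too few spontaneous events for peak analysis", call. = FALSE)
    return(out)
  }
  d <- density(log(spontRors), bw = "nrd0", adjust = 0.6)
  pp <- .peakProminence(d$y)
  keep <- pp$peaks[pp$prominence >= promFrac * max(d$y)]
  if (!length(keep)) keep <- pp$peaks[which.max(pp$prominence)]
  modes <- exp(d$x[keep])
  modes <- modes[modes >= min(spontRors) / 1.2 & modes <= max(spontRors) * 1.2]
  if (!length(modes)) return(out)
  ## refine the KDE modes with a lognormal-mixture EM: the trial-to-trial
  ## spread is lognormal, so a component's strength is exp(mu + sigma^2/2),
  ## which removes the mode-vs-mean bias of skewed event distributions
  comp <- .logMixtureEM(log(spontRors), log(sort(modes, decreasing = TRUE)))
  ## components whose means sit within their joint spread are one population
  ## rendered as KDE ripple, not separable inputs: merge them. The weak band
  ## (< 2.2 V/s) is held to a stricter separation standard because small
  ## inputs are known to be unresolvable individually there.
  repeat {
    if (nrow(comp) < 2) break
    mergedAny <- FALSE
    for (i in seq_len(nrow(comp) - 1)) {
      j <- i + 1L
      thrSep <- if (exp(comp$mu[i]) < 2.2 && exp(comp$mu[j]) < 2.2)
        max(1.4 * (comp$sigma[i] + comp$sigma[j]), 0.55) else
          comp$sigma[i] + comp$sigma[j]
      if (abs(comp$mu[i] - comp$mu[j]) < thrSep) {
        w <- comp$n_eff[c(i, j)]
        comp$mu[i] <- sum(w * comp$mu[c(i, j)]) / sum(w)
        comp$sigma[i] <- max(comp$sigma[c(i, j)])
        comp$n_eff[i] <- sum(w)
        comp <- comp[-j, , drop = FALSE]
        mergedAny <- TRUE
        break
      }
    }
    if (!mergedAny) break
  }
  for (i in seq_len(nrow(comp))) {
    if (comp$n_eff[i] < 3) next
    est <- exp(comp$mu[i] + comp$sigma[i]^2 / 2)
    if (!is.null(evokedInputs) && nrow(evokedInputs) &&
        any(abs(evokedInputs$mean_ror - est) <= matchTol *
              pmax(est, evokedInputs$mean_ror))) next
    if (nrow(out) && any(abs(out$mean_ror - est) <= matchTol * out$mean_ror)) next
    out[nrow(out) + 1L, ] <- list(est, est * comp$sigma[i], NA_real_, NA_real_,
                                  as.integer(round(comp$n_eff[i])),
                                  "spontaneous")
  }
  out[order(-out$mean_ror), , drop = FALSE]
}

## small Gaussian-mixture EM on log rates of rise, initialised at the KDE
## modes; variances floored to keep components from collapsing on ties
.logMixtureEM <- function(x, mu0, iters = 60L, sigmaFloor = 0.06) {
  K <- length(mu0)
  n <- length(x)
  mu <- mu0
  sigma <- rep(0.25, K)
  pi_ <- rep(1 / K, K)
  for (it in seq_len(iters)) {
    dens <- vapply(seq_len(K), function(k)
      pi_[k] * stats::dnorm(x, mu[k], sigma[k]), numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    nk <- colSums(r)
    nk[nk < 1e-8] <- 1e-8
    muNew <- colSums(r * x) / nk
    sigma <- pmax(sigmaFloor,
                  sqrt(colSums(r * (x - rep(muNew, each = n))^2) / nk))
    pi_ <- nk / n
    if (max(abs(muNew - mu)) < 1e-6) { mu <- muNew; break }
    mu <- muNew
  }
  data.frame(mu = mu, sigma = sigma, n_eff = colSums(
    vapply(seq_len(K), function(k) {
      dk <- pi_[k] * stats::dnorm(x, mu[k], sigma[k])
      tot <- rowSums(vapply(seq_len(K), function(j)
        pi_[j] * stats::dnorm(x, mu[j], sigma[j]), numeric(n)))
      tot[tot == 0] <- .Machine$double.xmin
      dk / tot
    }, numeric(n))))
}

#' Assemble a cell's input roster
#'
#' Deduplicates evoked and spontaneous input estimates (matching within
#' `matchTol` relative rate of rise and, when both latencies are known,
#' `latencyTol` ms; evoked provenance preferred), sorts by decreasing mean
#' rate of rise (ties broken by earlier latency), flags strong inputs
#' (rate of rise above `strongThreshold`, the discontinuity in the observed
#' input-strength distribution), and computes the competition index — the
#' ratio of the second strongest to the strongest input.
#'
#' @param evokedInputs,spontInputs candidate data.frames (see
#'   [scanRecruitment()], [spontPeakInputs()]).
#' @param age postnatal age, days.
#' @param strongThreshold V/s.
#' @param matchTol,latencyTol deduplication tolerances.
#' @return a [CellInputs-class] object.
#' @export
assembleCell <- function(evokedInputs, spontInputs = NULL, age = NA_real_,
                         strongThreshold = 10, matchTol = 0.20,
                         latencyTol = 0.5) {
  all <- rbind(evokedInputs,
               if (!is.null(spontInputs) && nrow(spontInputs)) spontInputs)
  if (is.null(all) || !nrow(all))
    stop("cell excluded: no inputs identified", call. = FALSE)
  all <- all[order(all$source != "evoked", -all$mean_ror), , drop = FALSE]
  keep <- rep(TRUE, nrow(all))
  for (i in seq_len(nrow(all))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(all))) {
      if (j <= i || !keep[j]) next
      sameRor <- abs(all$mean_ror[i] - all$mean_ror[j]) <=
        matchTol * max(all$mean_ror[i], all$mean_ror[j])
      bothLat <- !is.na(all$mean_latency[i]) && !is.na(all$mean_latency[j])
      sameLat <- !bothLat ||
        abs(all$mean_latency[i] - all$mean_latency[j]) <= latencyTol
      if (sameRor && sameLat) keep[j] <- FALSE
    }
  }
  inp <- all[keep, , drop = FALSE]
  ord <- order(-inp$mean_ror, inp$mean_latency)
  inp <- inp[ord, , drop = FALSE]
  inputs <- data.frame(
    mean_ror = inp$mean_ror, ror_sd = inp$ror_sd,
    mean_latency = inp$mean_latency, source = inp$source,
    strong = inp$mean_ror > strongThreshold,
    prespike = FALSE, prespike_amp = NA_real_, p_ap = NA_real_,
    crosschecked = if ("crosschecked" %in% names(inp)) inp$crosschecked else NA)
  ci <- if (nrow(inputs) >= 2) inputs$mean_ror[2] / inputs$mean_ror[1] else NA_real_
  new("CellInputs", age = as.numeric(age), inputs = inputs,
      competitionIndex = ci)
}

#' Identify a cell's synaptic inputs from its recordings
#'
#' End-to-end per-cell identification: detects EPSPs on the stimulation
#' trace, classifies evoked events, splits the latency distribution into
#' domains when bimodal (density minimum searched between 3 and 4 ms),
#' scans each domain's intensity groups for recruitment, cross-checks
#' candidates against the spontaneous rate-of-rise distribution, adds inputs
#' found only in spontaneous activity, and assembles the roster with
#' prespike presence (detected in at least half of an input's large events)
#' and AP-triggering efficacy per strong input.
#'
#' @param stimTrace stimulation [TraceRecording-class].
#' @param spontTrace spontaneous [TraceRecording-class] or NULL.
#' @param age postnatal age, days.
#' @param minRor,strongThreshold,tSumThreshold,minIncrease,latencyTol,crossTol
#'   analysis parameters with reference-protocol defaults.
#' @return a [CellInputs-class] object.
#' @export
identifyInputs <- function(stimTrace, spontTrace = NULL, age = NA_real_,
                           minRor = 0.7, strongThreshold = 10,
                           tSumThreshold = 6, minIncrease = 0.20,
                           latencyTol = 0.5, crossTol = 0.20) {
  ev <- detectEPSPs(stimTrace, minRor = minRor)
  ev <- classifyEvoked(ev, stimTrace)
  ev <- detectPrespikes(stimTrace, ev)

  spontRors <- numeric()
  if (!is.null(spontTrace) && length(spontTrace@samples)) {
    sev <- detectEPSPs(spontTrace, minRor = minRor)
    spontRors <- sev$ror
  }

  ## latency-domain split when the evoked latency distribution is bimodal
  lats <- ev$latency_ms[ev$evoked]
  domains <- list(c(1, 8))
  if (length(lats) >= 20) {
    dl <- density(lats, bw = "nrd0")
    sel <- dl$x > 3 & dl$x < 4
    if (any(sel)) {
      below <- sum(lats <= 3.5); above <- sum(lats > 3.5)
      if (below >= 5 && above >= 5) {
        valley <- dl$x[sel][which.min(dl$y[sel])]
        side <- range(dl$y[dl$x > 1.5 & dl$x < 3] , dl$y[dl$x > 4 & dl$x < 7])
        if (min(dl$y[sel]) < 0.8 * max(side))
          domains <- list(c(1, valley), c(valley, 8))
      }
    }
  }

  cands <- list()
  for (dom in domains) {
    gr <- groupByIntensity(ev, stimTrace, latencyDomain = dom)
    if (length(gr) >= 2) {
      cd <- scanRecruitment(gr, tSumThreshold = tSumThreshold,
                            minIncrease = minIncrease, latencyTol = latencyTol)
      if (nrow(cd)) cands[[length(cands) + 1L]] <- cd
    }
  }
  evokedInputs <- if (length(cands)) do.call(rbind, cands) else
    data.frame(mean_ror = numeric(), ror_sd = numeric(),
               mean_latency = numeric(), recruit_intensity = numeric(),
               n = integer(), source = character())

  ## spontaneous cross-check of evoked candidates
  if (nrow(evokedInputs)) {
    checked <- vapply(evokedInputs$mean_ror, function(r) {
      ok <- spontCrosscheck(r, spontRors, relTol = crossTol)
      as.logical(ok)
    }, logical(1))
    evokedInputs$crosschecked <- length(spontRors) > 0
    evokedInputs <- evokedInputs[checked, , drop = FALSE]
  }

  ## strong evoked estimates carry larger deconvolution/AP-truncation error,
  ## so spontaneous modes in the strong range are deduplicated against the
  ## evoked inputs with a wider tolerance than weak ones
  spontInputs <- spontPeakInputs(spontRors, evokedInputs,
                                 minEvents = 20L, matchTol = crossTol)
  if (nrow(spontInputs) && nrow(evokedInputs)) {
    dupStrong <- vapply(spontInputs$mean_ror, function(m)
      m > strongThreshold &&
        any(abs(evokedInputs$mean_ror - m) <=
              0.35 * pmax(m, evokedInputs$mean_ror)), logical(1))
    spontInputs <- spontInputs[!dupStrong, , drop = FALSE]
  }
  if (nrow(spontInputs)) spontInputs$crosschecked <- TRUE

  cell <- assembleCell(evokedInputs, spontInputs, age = age,
                       strongThreshold = strongThreshold,
                       latencyTol = latencyTol)

  ## prespike presence and P_AP for strong inputs
  inputs <- cell@inputs
  if (any(inputs$strong)) {
    aps <- detectAPs(stimTrace)$time_s
    for (i in which(inputs$strong)) {
      if (is.na(inputs$mean_latency[i])) next
      sel <- ev$evoked & abs(ev$ror - inputs$mean_ror[i]) <=
        0.35 * inputs$mean_ror[i] &
        abs(ev$latency_ms - inputs$mean_latency[i]) <= 0.75
      sub <- ev[sel & !is.na(sel), , drop = FALSE]
      if (!nrow(sub)) next
      if (mean(sub$prespike) >= 0.5) {
        inputs$prespike[i] <- TRUE
        inputs$prespike_amp[i] <- mean(sub$prespike_amp, na.rm = TRUE)
      }
      inputs$p_ap[i] <- computePAP(sub, aps)
    }
  }
  methods::initialize(cell, inputs = inputs)
}
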