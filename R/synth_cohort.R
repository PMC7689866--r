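#' @include AllClasses.R utils.R
NULL

#' Construct cohort-generation parameters
#'
#' Convenience constructor for [CohortParams-class]; any slot can be
#' overridden by name. Defaults encode the developmental conditions of the
#' reference dataset (see the class documentation).
#'
#' @param nCells number of cells.
#' @param seed integer seed.
#' @param ... further slots, e.g. `ageRange`, `strongestGrowth`,
#'   `strongestSDLog`, `beta`, `alpha`, `sfScatterSDLog`.
#' @return a validated `CohortParams` object.
#' @export
#' @examples
#' cohortParams(nCells = 4, seed = 7)
cohortParams <- function(nCells = 32L, seed = 1L, ...) {
  args <- list(...)
  obj <- new("CohortParams", nCells = as.integer(nCells), seed = as.integer(seed))
  for (nm in names(args)) {
    if (!nm %in% slotNames(obj))
      stop("unknown CohortParams field: ", nm, call. = FALSE)
    slot(obj, nm) <- if (nm %in% c("nCells", "seed")) as.integer(args[[nm]])
                     else args[[nm]]
  }
  validObject(obj)
  obj
}

#' Invert the structure-function power law
#'
#' Contact area implied by an EPSP rate of rise under
#' `ror = beta * area^alpha`.
#'
#' @param ror rate of rise, V/s.
#' @param beta,alpha power-law parameters.
#' @return contact area, µm².
#' @export
#' @examples
#' areaFromRoR(6.8)  # 1 um^2 by construction
areaFromRoR <- function(ror, beta = 6.8, alpha = 0.35) {
  stopifnot1(all(ror > 0) && beta > 0 && alpha > 0,
             "ror, beta and alpha must be positive")
  (ror / beta)^(1 / alpha)
}

#' Generate a synthetic cohort with full ground truth
#'
#' Draws per-cell ages, input counts and input strengths following the
#' developmental model: the strongest input grows linearly with age
#' (`strongestIntercept + strongestGrowth * (age - 2)` V/s with lognormal
#' cell-to-cell spread), the second strongest is stationary around
#' `secondMean`, and the remaining inputs are weak (uniform over `weakRange`).
#' Each input's true somatic contact area is set from the power law applied to
#' its latent (pre-scatter) strength, so with all spreads at zero
#' `beta * area^alpha` reproduces `true_ror` exactly.
#'
#' @param params a [CohortParams-class] object.
#' @return list of [CellGroundTruth-class] objects, length `nCells`.
#' @export
#' @examples
#' cells <- makeCohort(cohortParams(nCells = 3, seed = 11))
#' cells[[1]]
makeCohort <- function(params) {
  stopifnot1(is(params, "CohortParams"), "params must be a CohortParams object")
  validObject(params)
  withSeed(params@seed, {
    lapply(seq_len(params@nCells), function(i) .makeCell(params))
  })
}

## mean-one lognormal multiplier
lnormMult <- function(n, sdlog) {
  if (sdlog <= 0) return(rep(1, n))
  exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

.makeCell <- function(p) {
  age <- runif(1, p@ageRange[1], p@ageRange[2])
  nIn <- max(2L, as.integer(round(rnormTrunc(1, p@nInputsMean, p@nInputsSD, 2))))

  devStrongest <- (p@strongestIntercept + p@strongestGrowth * (age - 2)) *
    lnormMult(1, p@strongestSDLog)
  devSecond <- p@secondMean * lnormMult(1, p@secondSDLog)
  devWeak <- if (nIn > 2) runif(nIn - 2, p@weakRange[1], p@weakRange[2]) else numeric()
  dev <- c(devStrongest, devSecond, devWeak)

  trueRor <- dev * lnormMult(nIn, p@sfScatterSDLog)
  areas <- areaFromRoR(dev, p@beta, p@alpha)

  ord <- order(trueRor, decreasing = TRUE)
  dev <- dev[ord]; trueRor <- trueRor[ord]; areas <- areas[ord]

  thr <- runif(nIn, 0.08, 0.40)
  actP <- pmin(1, pmax(0.59, rnorm(nIn, 0.83, 0.12)))

  lat <- numeric(nIn)
  lat[1] <- min(2.5, max(1.6, rnorm(1, 2.1, 0.3)))   # strongest: short latency
  if (nIn > 1) {
    early <- runif(nIn - 1) < 0.4
    lat[-1] <- ifelse(early, runif(nIn - 1, 1.5, 3), runif(nIn - 1, 4, 8))
  }
  latCV <- pmin(0.038, pmax(0.010, rnorm(nIn, 0.023, 0.009)))

  calyceal <- rep(FALSE, nIn)
  preAmp <- rep(0, nIn)
  if (trueRor[1] > 10 && runif(1) < stats::plogis((age - 4.1) / 0.7)) {
    calyceal[1] <- TRUE
    preAmp[1] <- runif(1, 0.1, 0.4)
  }

  inputs <- data.frame(
    true_ror = trueRor,
    dev_ror = dev,
    recruitment_threshold = thr,
    activation_prob = actP,
    latency_mean = lat,
    latency_cv = latCV,
    is_calyceal = calyceal,
    prespike_amp = preAmp,
    ror_trial_cv = runif(nIn, p@rorNoiseCV[1], p@rorNoiseCV[2])
  )

  soma <- min(9, max(5, rnorm(1, 7, 1)))
  new("CellGroundTruth", age = age, inputs = inputs,
      trueContactAreas = areas, somaRadius = soma)
}
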