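#' @include utils.R
NULL

## ------------------------------------------------------------------
## Physiology containers
## ------------------------------------------------------------------

#' TraceRecording: a membrane-potential time series
#'
#' Holds a single-channel current-clamp recording (mV) with its sampling rate,
#' the afferent stimulation events delivered during the recording, the resting
#' potential, and free-form metadata (for synthetic traces this includes the
#' ground-truth event table).
#'
#' @slot samples numeric vector of membrane potential, mV.
#' @slot samplingRate sampling frequency, Hz (25 kHz in the reference setup).
#' @slot stimuli data.frame with columns `time_s`, `intensity_mA` (0 rows when
#'   no stimulation was applied).
#' @slot restingPotential resting membrane potential, mV.
#' @slot metadata list; synthetic traces carry `groundTruth` (data.frame of
#'   inserted events), `seed`, `sweepLength_s` and related provenance.
#' @exportClass TraceRecording
setClass("TraceRecording",
  representation(samples = "numeric", samplingRate = "numeric",
                 stimuli = "data.frame", restingPotential = "numeric",
                 metadata = "list"),
  prototype(samples = numeric(), samplingRate = 25000,
            stimuli = data.frame(time_s = numeric(), intensity_mA = numeric()),
            restingPotential = -70, metadata = list()))

setValidity("TraceRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  st <- object@stimuli
  if (!all(c("time_s", "intensity_mA") %in% names(st)))
    msg <- c(msg, "stimuli needs columns time_s, intensity_mA")
  else if (nrow(st)) {
    dur <- length(object@samples) / object@samplingRate
    if (any(diff(st$time_s) <= 0))
      msg <- c(msg, "stimulus times must be strictly increasing")
    if (any(st$time_s < 0) || any(st$time_s > dur))
      msg <- c(msg, "stimulus times must lie within the trace")
  }
  if (length(msg)) msg else TRUE
})

#' CellInputs: the identified synaptic inputs of one cell
#'
#' @slot age postnatal age, days.
#' @slot inputs data.frame, one row per identified input, sorted by decreasing
#'   mean rate of rise; columns `mean_ror` (V/s), `ror_sd`, `mean_latency`
#'   (ms, NA for inputs identified from spontaneous activity only), `source`
#'   ("evoked"/"spontaneous"), `strong`, `prespike`, `prespike_amp`, `p_ap`,
#'   `crosschecked`.
#' @slot competitionIndex ratio of the second strongest to the strongest
#'   input's mean rate of rise; NA when fewer than two inputs.
#' @exportClass CellInputs
setClass("CellInputs",
  representation(age = "numeric", inputs = "data.frame",
                 competitionIndex = "numeric"),
  prototype(age = NA_real_, inputs = data.frame(), competitionIndex = NA_real_))

setValidity("CellInputs", function(object) {
  inp <- object@inputs
  if (nrow(inp) == 0) return("analyzed cells must have at least one input")
  if (any(inp$mean_ror <= 0)) return("mean_ror must be positive")
  if (is.unsorted(rev(inp$mean_ror))) return("inputs must be sorted by decreasing mean_ror")
  ci <- object@competitionIndex
  if (!is.na(ci) && (ci <= 0 || ci > 1 + 1e-12))
    return("competitionIndex must lie in (0, 1]")
  TRUE
})

## ------------------------------------------------------------------
## Synthetic-cohort parameters and ground truth
## ------------------------------------------------------------------

#' CohortParams: generative parameters for a synthetic cohort
#'
#' Defaults are the study conditions of the reference dataset: strongest-input
#' growth 4.2 V/s per day from 8 V/s at P2, a stationary second-strongest
#' input around 3.7 V/s, 5.6 +/- 1.6 inputs per cell, weak inputs at
#' 0.7-2 V/s, trial-to-trial rate-of-rise CV 7-38%, and the structure-function
#' law EPSP (V/s) = beta * area^alpha with beta = 6.8, alpha = 0.35.
#'
#' @slot nCells number of cells to simulate.
#' @slot ageRange postnatal age range in days (uniform draw), within 2-8.
#' @slot strongestGrowth V/s per day growth of the strongest input.
#' @slot strongestIntercept strongest-input mean at age 2, V/s.
#' @slot strongestSDLog lognormal cell-to-cell spread (sdlog) of the strongest
#'   input around its age trend.
#' @slot secondMean mean of the second strongest input, V/s.
#' @slot secondSDLog lognormal spread (sdlog) of the second strongest input.
#' @slot nInputsMean,nInputsSD truncated-normal input count per cell (min 2).
#' @slot weakRange rate-of-rise range of the remaining weak inputs, V/s.
#' @slot beta,alpha structure-function power law parameters.
#' @slot sfScatterSDLog mean-one lognormal scatter of realised input strength
#'   around the power law; the default reproduces a log-scale structure-
#'   function correlation near 0.8.
#' @slot rorNoiseCV range of the per-trial rate-of-rise coefficient of
#'   variation, drawn uniformly per input.
#' @slot seed integer RNG seed.
#' @exportClass CohortParams
setClass("CohortParams",
  representation(nCells = "integer", ageRange = "numeric",
                 strongestGrowth = "numeric", strongestIntercept = "numeric",
                 strongestSDLog = "numeric", secondMean = "numeric",
                 secondSDLog = "numeric", nInputsMean = "numeric",
                 nInputsSD = "numeric", weakRange = "numeric",
                 beta = "numeric", alpha = "numeric",
                 sfScatterSDLog = "numeric", rorNoiseCV = "numeric",
                 seed = "integer"),
  prototype(nCells = 32L, ageRange = c(2, 8), strongestGrowth = 4.2,
            strongestIntercept = 8.0, strongestSDLog = 0.25, secondMean = 3.7,
            secondSDLog = 0.30, nInputsMean = 5.6, nInputsSD = 1.6,
            weakRange = c(0.7, 2), beta = 6.8, alpha = 0.35,
            sfScatterSDLog = 0.36, rorNoiseCV = c(0.07, 0.38), seed = 1L))

setValidity("CohortParams", function(object) {
  msg <- character()
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@beta <= 0) msg <- c(msg, "beta must be > 0")
  if (length(object@ageRange) != 2 || object@ageRange[1] < 2 ||
      object@ageRange[2] > 8 || object@ageRange[1] > object@ageRange[2])
    msg <- c(msg, "ageRange must lie within [2, 8]")
  if (object@strongestIntercept <= 0 || object@secondMean <= 0 ||
      any(object@weakRange <= 0))
    msg <- c(msg, "all rates of rise must be positive")
  if (length(msg)) msg else TRUE
})

#' CellGroundTruth: generative truth for one synthetic cell
#'
#' @slot age postnatal age, days.
#' @slot inputs data.frame, one row per input: `true_ror` (V/s),
#'   `recruitment_threshold` (mA), `activation_prob`, `latency_mean` (ms),
#'   `latency_cv`, `is_calyceal`, `prespike_amp` (mV, 0 when absent),
#'   `ror_trial_cv`.
#' @slot trueContactAreas µm² somatic contact area per input (same order).
#' @slot somaRadius soma radius, µm.
#' @exportClass CellGroundTruth
setClass("CellGroundTruth",
  representation(age = "numeric", inputs = "data.frame",
                 trueContactAreas = "numeric", somaRadius = "numeric"),
  prototype(age = 4, inputs = data.frame(), trueContactAreas = numeric(),
            somaRadius = 5))

setValidity("CellGroundTruth", function(object) {
  inp <- object@inputs
  msg <- character()
  if (nrow(inp)) {
    if (sum(inp$is_calyceal) > 1) msg <- c(msg, "at most one calyceal input")
    if (any(inp$latency_mean <= 1 | inp$latency_mean > 8))
      msg <- c(msg, "latency_mean must lie in (1, 8] ms")
    if (any(inp$activation_prob < 0.59 | inp$activation_prob > 1))
      msg <- c(msg, "activation_prob must lie in [0.59, 1]")
    if (any(inp$true_ror <= 0)) msg <- c(msg, "true_ror must be positive")
  }
  if (any(object@trueContactAreas < 0)) msg <- c(msg, "contact areas must be >= 0")
  if (length(msg)) msg else TRUE
})

#' VolumeParams: voxelisation, PSF and noise for synthetic volumes
#'
#' @slot voxelSize physical voxel size (z, y, x) in µm; default 0.110 axial,
#'   0.041 lateral (the reconstructed SIM sampling).
#' @slot psfSigma Gaussian PSF sigma per axis (z, y, x), µm; 0 disables.
#' @slot noiseModel list with `gaussian_sd` (intensity units) and
#'   `poisson_scale` (photon scaling; 0 disables shot noise).
#' @slot shellThickness radial thickness of the marker shell caps, µm.
#' @slot cleftGap radial gap between soma surface and marker shell, µm
#'   (synaptic cleft stand-in; targeted by the dilation optimisation).
#' @slot anisotropy z semi-axis scaling of the soma (1 = sphere).
#' @slot marginVoxels empty margin around the soma, voxels.
#' @slot intensity signal plateau intensity, arbitrary units.
#' @slot seed integer RNG seed.
#' @exportClass VolumeParams
setClass("VolumeParams",
  representation(voxelSize = "numeric", psfSigma = "numeric",
                 noiseModel = "list", shellThickness = "numeric",
                 cleftGap = "numeric", anisotropy = "numeric",
                 marginVoxels = "integer", intensity = "numeric",
                 seed = "integer"),
  prototype(voxelSize = c(0.110, 0.041, 0.041), psfSigma = c(0.12, 0.06, 0.06),
            noiseModel = list(gaussian_sd = 4, poisson_scale = 0.5),
            shellThickness = 0.45, cleftGap = 0.30, anisotropy = 1,
            marginVoxels = 12L, intensity = 100, seed = 1L))

setValidity("VolumeParams", function(object) {
  msg <- character()
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers (z, y, x)")
  if (object@shellThickness < object@voxelSize[2])
    msg <- c(msg, "shellThickness must be at least one lateral voxel")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------
## Imaging containers
## ------------------------------------------------------------------

#' VoxelVolume: a 3D intensity grid
#'
#' Arrays are stored ZYX: `dim = c(nz, ny, nx)`, matching the page order of
#' the multi-page TIFF interchange format.
#'
#' @slot intensities 3D numeric array (ZYX).
#' @slot voxelSize physical voxel size (z, y, x), µm.
#' @slot channelName channel label, e.g. "fill" (biocytin) or "marker" (VGluT).
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(intensities = "array", voxelSize = "numeric",
                 channelName = "character"))

setValidity("VoxelVolume", function(object) {
  if (length(dim(object@intensities)) != 3) return("intensities must be a 3D array")
  if (any(dim(object@intensities) < 1)) return("all dimensions must be >= 1")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers (z, y, x)")
  TRUE
})

#' SomaMask: segmented cell body
#'
#' @slot mask 3D logical array (ZYX), a single 26-connected component.
#' @slot voxelSize physical voxel size (z, y, x), µm.
#' @slot surfaceArea estimated surface area, µm².
#' @slot dilationUsed dilation applied, µm (0 before optimisation).
#' @exportClass SomaMask
setClass("SomaMask",
  representation(mask = "array", voxelSize = "numeric",
                 surfaceArea = "numeric", dilationUsed = "numeric"),
  prototype(surfaceArea = NA_real_, dilationUsed = 0))

setValidity("SomaMask", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3)
    return("mask must be a 3D logical array")
  if (object@dilationUsed < 0) return("dilationUsed must be >= 0")
  TRUE
})

#' ClusterSet: labelled marker clusters
#'
#' @slot labels 3D integer array (ZYX); 0 = background, clusters labelled
#'   densely from 1, each 26-connected and pairwise disjoint.
#' @slot voxelCounts integer vector of voxels per cluster (index = label).
#' @slot thresholdUsed intensity threshold that produced the clusters.
#' @slot voxelSize physical voxel size (z, y, x), µm.
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(labels = "array", voxelCounts = "integer",
                 thresholdUsed = "numeric", voxelSize = "numeric"))

setValidity("ClusterSet", function(object) {
  if (length(dim(object@labels)) != 3) return("labels must be a 3D array")
  k <- length(object@voxelCounts)
  if (k > 0 && max(object@labels) != k)
    return("labels must be dense from 1 to length(voxelCounts)")
  TRUE
})

#' ContactReport: per-cluster somatic contact accounting
#'
#' @slot clusterArea µm² somatic contact area per cluster (index = label).
#' @slot totalContactArea sum of per-cluster contact areas, µm².
#' @slot somaSurfaceArea estimated (dilated) soma surface area, µm².
#' @slot coverageFraction fraction of the soma surface contacted by clusters.
#' @slot largestArea,secondLargestArea the two largest contact areas, µm².
#' @slot contactRatio largestArea / totalContactArea, in (0, 1].
#' @slot metadata list (dilation used, estimator, provenance).
#' @exportClass ContactReport
setClass("ContactReport",
  representation(clusterArea = "numeric", totalContactArea = "numeric",
                 somaSurfaceArea = "numeric", coverageFraction = "numeric",
                 largestArea = "numeric", secondLargestArea = "numeric",
                 contactRatio = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("ContactReport", function(object) {
  msg <- character()
  if (abs(object@totalContactArea - sum(object@clusterArea)) >
      1e-6 * max(1, object@totalContactArea))
    msg <- c(msg, "totalContactArea must equal the sum of per-cluster areas")
  if (!is.na(object@coverageFraction) &&
      (object@coverageFraction < 0 || object@coverageFraction > 1))
    msg <- c(msg, "coverageFraction must lie in [0, 1]")
  if (!is.na(object@contactRatio) && object@totalContactArea > 0 &&
      (object@contactRatio <= 0 || object@contactRatio > 1 + 1e-12))
    msg <- c(msg, "contactRatio must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------
## Fit results
## ------------------------------------------------------------------

#' PowerLawFit: log-log OLS fit of EPSP rate of rise vs contact area
#'
#' @slot beta,alpha parameters of ror = beta * area^alpha.
#' @slot seBeta,seAlpha standard errors (delta method for beta).
#' @slot rLog Pearson correlation of the log-transformed pairs.
#' @slot Fstat,p overall regression F (df 1, n-2) and two-sided p.
#' @slot n number of cells.
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  representation(beta = "numeric", alpha = "numeric", seBeta = "numeric",
                 seAlpha = "numeric", rLog = "numeric", Fstat = "numeric",
                 p = "numeric", n = "integer"))

#' LogisticFit: maximum-likelihood logistic onset fit
#'
#' Fits P(present | age) = 1 / (1 + exp(-(age - m)/s)).
#'
#' @slot midpoint m, days.
#' @slot steepness s, days.
#' @slot seM,seS delta-method standard errors.
#' @slot converged FALSE when (quasi-)separation was detected.
#' @exportClass LogisticFit
setClass("LogisticFit",
  representation(midpoint = "numeric", steepness = "numeric", seM = "numeric",
                 seS = "numeric", converged = "logical"))

setValidity("LogisticFit", function(object) {
  if (isTRUE(object@converged) && object@steepness <= 0)
    return("steepness must be positive for a converged fit")
  TRUE
})
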