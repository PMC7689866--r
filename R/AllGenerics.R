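#' @include AllClasses.R
NULL

#' Accessors for calyxSFR containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `traceSamples`, `samplingRate`, `stimuli`, `restingPotential`,
#' `voxelSize`, `intensities`, `maskArray`, `clusterLabels`,
#' `inputEstimates`, `competitionIndex`, `clusterAreas`, `contactRatio`,
#' `coverageFraction`.
#'
#' @param object a calyxSFR object.
#' @return the corresponding component.
#' @name accessors
#' @aliases traceSamples samplingRate stimuli restingPotential voxelSize
#'   intensities maskArray clusterLabels inputEstimates competitionIndex
#'   clusterAreas contactRatio coverageFraction
NULL

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(object) standardGeneric("traceSamples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("stimuli", function(object) standardGeneric("stimuli"))
#' @rdname accessors
#' @export
setGeneric("restingPotential", function(object) standardGeneric("restingPotential"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("inputEstimates", function(object) standardGeneric("inputEstimates"))
#' @rdname accessors
#' @export
setGeneric("competitionIndex", function(object) standardGeneric("competitionIndex"))
#' @rdname accessors
#' @export
setGeneric("clusterAreas", function(object) standardGeneric("clusterAreas"))
#' @rdname accessors
#' @export
setGeneric("contactRatio", function(object) standardGeneric("contactRatio"))
#' @rdname accessors
#' @export
setGeneric("coverageFraction", function(object) standardGeneric("coverageFraction"))

#' @rdname accessors
setMethod("traceSamples", "TraceRecording", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "TraceRecording", function(object) object@samplingRate)
#' @rdname accessors
setMethod("stimuli", "TraceRecording", function(object) object@stimuli)
#' @rdname accessors
setMethod("restingPotential", "TraceRecording", function(object) object@restingPotential)
#' @rdname accessors
setMethod("voxelSize", "VoxelVolume", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "SomaMask", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "ClusterSet", function(object) object@voxelSize)
#' @rdname accessors
setMethod("intensities", "VoxelVolume", function(object) object@intensities)
#' @rdname accessors
setMethod("maskArray", "SomaMask", function(object) object@mask)
#' @rdname accessors
setMethod("clusterLabels", "ClusterSet", function(object) object@labels)
#' @rdname accessors
setMethod("inputEstimates", "CellInputs", function(object) object@inputs)
#' @rdname accessors
setMethod("competitionIndex", "CellInputs", function(object) object@competitionIndex)
#' @rdname accessors
setMethod("clusterAreas", "ContactReport", function(object) object@clusterArea)
#' @rdname accessors
setMethod("contactRatio", "ContactReport", function(object) object@contactRatio)
#' @rdname accessors
setMethod("coverageFraction", "ContactReport", function(object) object@coverageFraction)

setMethod("show", "TraceRecording", function(object) {
  dur <- length(object@samples) / object@samplingRate
  cat(sprintf("TraceRecording: %.3f s at %g kHz, %d stimuli, rest %.1f mV\n",
              dur, object@samplingRate / 1000, nrow(object@stimuli),
              object@restingPotential))
})

setMethod("show", "CellInputs", function(object) {
  cat(sprintf("CellInputs: P%.1f, %d inputs, competition index %s\n",
              object@age, nrow(object@inputs),
              ifelse(is.na(object@competitionIndex), "NA",
                     sprintf("%.2f", object@competitionIndex))))
  print(head(object@inputs[, c("mean_ror", "mean_latency", "source", "strong")], 8))
})

setMethod("show", "CellGroundTruth", function(object) {
  cat(sprintf("CellGroundTruth: P%.1f, %d inputs (strongest %.1f V/s), soma %.1f um\n",
              object@age, nrow(object@inputs),
              if (nrow(object@inputs)) max(object@inputs$true_ror) else NA,
              object@somaRadius))
})

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VoxelVolume '%s': %d x %d x %d (ZYX), voxel %.3f x %.3f x %.3f um\n",
              object@channelName, d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "SomaMask", function(object) {
  cat(sprintf("SomaMask: %d voxels, surface %.1f um^2, dilation %.3f um\n",
              sum(object@mask), object@surfaceArea, object@dilationUsed))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters (threshold %.3g), sizes %s\n",
              length(object@voxelCounts), object@thresholdUsed,
              paste(head(sort(object@voxelCounts, decreasing = TRUE), 6),
                    collapse = ", ")))
})

setMethod("show", "ContactReport", function(object) {
  cat(sprintf(paste0("ContactReport: %d clusters, total contact %.1f um^2, ",
                     "largest %.1f um^2, contact ratio %.2f, coverage %.3f\n"),
              length(object@clusterArea), object@totalContactArea,
              object@largestArea, object@contactRatio,
              object@coverageFraction))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: ror = %.2f * area^%.3f (se %.2f / %.3f), r_log %.2f, F %.3g, p %.3g, n %d\n",
              object@beta, object@alpha, object@seBeta, object@seAlpha,
              object@rLog, object@Fstat, object@p, object@n))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit: midpoint %.2f d, steepness %.2f d (se %.2f / %.2f)%s\n",
              object@midpoint, object@steepness, object@seM, object@seS,
              if (object@converged) "" else " [non-converged: separation]"))
})
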