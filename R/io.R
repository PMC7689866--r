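#' @include AllClasses.R
NULL

#' Read and write traces, events and volumes
#'
#' Traces travel as a values CSV (`time_s,voltage_mV`) plus a JSON sidecar
#' (`sampling_hz`, `resting_mV`, `stimuli`, `seed`, ground-truth event table
#' when present). Volumes travel as one multi-page TIFF per channel (ZYX page
#' order, intensities rescaled with the scale recorded) plus a JSON
#' sidecar with the voxel size. Rescaling maps intensities to the unit
#' interval for 16-bit storage and is undone on read.
#'
#' @param trace a [TraceRecording-class].
#' @param prefix file path prefix; writes `<prefix>.csv` + `<prefix>.json`.
#' @return `writeTrace`/`writeVolume` return the prefix invisibly;
#'   `readTrace` a [TraceRecording-class]; `readVolume` a
#'   [VoxelVolume-class]; `readEvents`/`writeEvents` a data.frame / path.
#' @name traceIO
NULL

#' @rdname traceIO
#' @export
writeTrace <- function(trace, prefix) {
  fs <- trace@samplingRate
  df <- data.frame(time_s = (seq_along(trace@samples) - 1) / fs,
                   voltage_mV = trace@samples)
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(sampling_hz = fs, resting_mV = trace@restingPotential,
               stimuli = trace@stimuli, metadata = trace@metadata)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname traceIO
#' @export
readTrace <- function(prefix) {
  df <- read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  stim <- as.data.frame(side$stimuli)
  if (!nrow(stim)) stim <- data.frame(time_s = numeric(), intensity_mA = numeric())
  meta <- side$metadata
  if (is.null(meta)) meta <- list()
  new("TraceRecording", samples = df$voltage_mV,
      samplingRate = side$sampling_hz, stimuli = stim,
      restingPotential = side$resting_mV, metadata = as.list(meta))
}

#' @rdname traceIO
#' @param events event table.
#' @param file TSV path.
#' @export
writeEvents <- function(events, file) {
  write.table(events, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname traceIO
#' @export
readEvents <- function(file) {
  read.delim(file)
}

#' @rdname traceIO
#' @param volume a [VoxelVolume-class].
#' @export
writeVolume <- function(volume, prefix) {
  a <- volume@intensities
  lo <- min(a); hi <- max(a)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(a)[1]), function(z) (a[z, , ] - lo) / scale)
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16L)
  jsonlite::write_json(
    list(voxel_size_um = volume@voxelSize, channel = volume@channelName,
         intensity_offset = lo, intensity_scale = scale,
         dim_zyx = dim(a)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname traceIO
#' @export
readVolume <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  d <- as.integer(side$dim_zyx)
  a <- array(0, d)
  for (z in seq_len(d[1]))
    a[z, , ] <- pages[[z]] * side$intensity_scale + side$intensity_offset
  new("VoxelVolume", intensities = a, voxelSize = as.numeric(side$voxel_size_um),
      channelName = as.character(side$channel))
}
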