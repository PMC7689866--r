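#' @include AllClasses.R utils.R synth_cohort.R
NULL

#' Construct volume-generation parameters
#'
#' Convenience constructor for [VolumeParams-class]; any slot can be
#' overridden by name (e.g. a coarser `voxelSize` for quick simulations, or
#' `psfSigma = c(0, 0, 0)` and `noiseModel = list(gaussian_sd = 0,
#' poisson_scale = 0)` for noise-free geometry).
#'
#' @param seed integer seed.
#' @param ... slots to override.
#' @return a validated `VolumeParams` object.
#' @export
volumeParams <- function(seed = 1L, ...) {
  args <- list(...)
  obj <- new("VolumeParams", seed = as.integer(seed))
  for (nm in names(args)) {
    if (!nm %in% slotNames(obj))
      stop("unknown VolumeParams field: ", nm, call. = FALSE)
    slot(obj, nm) <- if (nm %in% c("seed", "marginVoxels")) as.integer(args[[nm]])
                     else args[[nm]]
  }
  validObject(obj)
  obj
}

## spherical-cap half-angle for a requested surface area on a sphere of
## radius r: A = 2 pi r^2 (1 - cos(theta))
capAngle <- function(area, r) {
  c <- 1 - area / (2 * pi * r^2)
  if (c <= -1) stop("requested cap area exceeds the soma surface", call. = FALSE)
  acos(max(-1, min(1, c)))
}

## random unit vectors with pairwise angular separations >= sep[i] + sep[j]
placeCaps <- function(thetas, gapAngle, maxTries = 4000L) {
  k <- length(thetas)
  dirs <- matrix(NA_real_, k, 3)
  for (i in seq_len(k)) {
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      ok <- TRUE
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          ang <- acos(max(-1, min(1, sum(u * dirs[j, ]))))
          if (ang < thetas[i] + thetas[j] + gapAngle) { ok <- FALSE; break }
        }
      }
      if (ok) { dirs[i, ] <- u; placed <- TRUE; break }
    }
    if (!placed)
      stop("cap placement failed (overlapping caps); regenerate with a new seed",
           call. = FALSE)
  }
  dirs
}

#' Generate a synthetic two-channel volume with ground truth
#'
#' The fill channel is a solid sphere of radius `somaRadius` (optionally
#' z-stretched by `anisotropy`); the marker channel consists of spherical-cap
#' shells apposed to the soma surface — one per input whose true contact area
#' is at least `minCapArea` — separated from the soma by `cleftGap` and from
#' each other by at least two voxels, so clusters are disconnected by
#' construction. Both channels are blurred by the Gaussian PSF and corrupted
#' by the noise model. The returned truth report is computed from the exact
#' cap construction (analytic spherical-cap areas, evaluated at the cleft
#' interface `somaRadius + cleftGap` — the surface the dilation-optimised
#' measurement probes).
#'
#' @param cell a [CellGroundTruth-class].
#' @param vparams a [VolumeParams-class].
#' @param minCapArea smallest cap rendered, µm².
#' @param capDirs optional matrix of unit cap directions (rows, ZYX) to use
#'   instead of random placement (e.g. a controlled equatorial cap for
#'   calibration geometries).
#' @return list with `fill` and `marker` ([VoxelVolume-class]), `truth`
#'   (a [ContactReport-class] from the analytic geometry), `labelArray`
#'   (noise-free cap labels) and `capAreas` (µm², one per rendered cap, in
#'   decreasing input-strength order).
#' @export
synthVolume <- function(cell, vparams = volumeParams(), minCapArea = 0.1,
                        capDirs = NULL) {
  stopifnot1(is(cell, "CellGroundTruth"), "cell must be a CellGroundTruth")
  stopifnot1(is(vparams, "VolumeParams"), "vparams must be a VolumeParams")
  vs <- vparams@voxelSize
  r <- cell@somaRadius
  az <- vparams@anisotropy
  areas <- cell@trueContactAreas
  areas <- areas[areas >= minCapArea]
  areas <- sort(areas, decreasing = TRUE)
  ## contact areas are defined at the cleft interface (radius r + cleftGap),
  ## which is the surface the dilation-optimised measurement probes
  rc <- r + vparams@cleftGap
  if (length(areas) && max(areas) > 0.75 * 4 * pi * rc^2)
    stop("largest cap does not fit on the soma", call. = FALSE)

  pad <- vparams@cleftGap + vparams@shellThickness +
    vparams@marginVoxels * max(vs)
  halfZ <- r * az + pad
  halfL <- r + pad
  d <- c(2 * ceiling(halfZ / vs[1]) + 1, 2 * ceiling(halfL / vs[2]) + 1,
         2 * ceiling(halfL / vs[3]) + 1)

  zc <- (seq_len(d[1]) - (d[1] + 1) / 2) * vs[1]
  yc <- (seq_len(d[2]) - (d[2] + 1) / 2) * vs[2]
  xc <- (seq_len(d[3]) - (d[3] + 1) / 2) * vs[3]
  ## normalised radial coordinate (sphere after z-compression)
  rho <- sqrt(outer(outer((zc / az)^2, yc^2, "+"), xc^2, "+"))
  dim(rho) <- d

  withSeed(vparams@seed, {
    fill <- array(0, d)
    fill[rho <= r] <- vparams@intensity

    marker <- array(0, d)
    labelArray <- array(0L, d)
    if (length(areas)) {
      thetas <- vapply(areas, capAngle, numeric(1), r = rc)
      gapAngle <- 3 * vs[2] / r
      dirs <- if (is.null(capDirs)) placeCaps(thetas, gapAngle) else
        capDirs / sqrt(rowSums(capDirs^2))
      shellSel <- which(rho > r + vparams@cleftGap &
                          rho <= r + vparams@cleftGap + vparams@shellThickness)
      ai <- arrayInd(shellSel, d)
      ux <- xc[ai[, 3]]; uy <- yc[ai[, 2]]; uz <- zc[ai[, 1]] / az
      nrm <- sqrt(ux^2 + uy^2 + uz^2)
      for (i in seq_along(areas)) {
        cosang <- (uz * dirs[i, 1] + uy * dirs[i, 2] + ux * dirs[i, 3]) / nrm
        sel <- shellSel[cosang >= cos(thetas[i])]
        marker[sel] <- vparams@intensity
        labelArray[sel] <- i
      }
    }

    blurNoise <- function(a) {
      if (any(vparams@psfSigma > 0)) a <- gaussBlur3d(a, vparams@psfSigma / vs)
      nm <- vparams@noiseModel
      ps <- if (is.null(nm$poisson_scale)) 0 else nm$poisson_scale
      gs <- if (is.null(nm$gaussian_sd)) 0 else nm$gaussian_sd
      if (ps > 0) a <- array(rpois(length(a), pmax(0, a) * ps) / ps, dim(a))
      if (gs > 0) a <- a + rnorm(length(a), 0, gs)
      ## fluorescence counts are non-negative
      pmax(a, 0)
    }
    fillN <- blurNoise(fill)
    markerN <- blurNoise(marker)

    somaSurf <- 4 * pi * rc^2 * if (az == 1) 1 else {
      ## prolate/oblate spheroid surface
      a <- rc; c <- rc * az
      if (abs(az - 1) < 1e-9) 1 else if (az > 1) {
        e <- sqrt(1 - (a / c)^2)
        (2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))) / (4 * pi * r^2)
      } else {
        e <- sqrt(1 - (c / a)^2)
        (2 * pi * a^2 * (1 + ((1 - e^2) / e) * atanh(e))) / (4 * pi * r^2)
      }
    }
    total <- sum(areas)
    truth <- new("ContactReport",
                 clusterArea = areas, totalContactArea = total,
                 somaSurfaceArea = somaSurf,
                 coverageFraction = min(1, total / somaSurf),
                 largestArea = if (length(areas)) areas[1] else 0,
                 secondLargestArea = if (length(areas) >= 2) areas[2] else 0,
                 contactRatio = if (total > 0) areas[1] / total else NA_real_,
                 metadata = list(analytic = TRUE, somaRadius = r,
                                 seed = vparams@seed))

    list(fill = new("VoxelVolume", intensities = fillN, voxelSize = vs,
                    channelName = "fill"),
         marker = new("VoxelVolume", intensities = markerN, voxelSize = vs,
                      channelName = "marker"),
         truth = truth, labelArray = labelArray, capAreas = areas)
  })
}
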