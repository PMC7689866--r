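#' @include AllClasses.R utils.R
NULL

asIntensityArray <- function(volume) {
  if (is(volume, "VoxelVolume")) volume@intensities else volume
}

#' IsoData (iterative intermeans) threshold
#'
#' Fixed point of `T -> (mean(I <= T) + mean(I > T)) / 2`, iterated from the
#' midrange until convergence.
#'
#' @param volume a [VoxelVolume-class] or numeric array/vector.
#' @param tol convergence tolerance as a fraction of the intensity range.
#' @return the converged threshold (intensity units).
#' @export
#' @examples
#' isodataThreshold(c(rep(10, 50), rep(90, 50)))  # 50
isodataThreshold <- function(volume, tol = 1e-7) {
  x <- as.numeric(asIntensityArray(volume))
  rng <- range(x)
  if (diff(rng) == 0)
    stop("cannot threshold a constant volume", call. = FALSE)
  T <- mean(rng)
  for (i in 1:200) {
    lo <- x <= T
    if (all(lo) || !any(lo)) break
    Tn <- (mean(x[lo]) + mean(x[!lo])) / 2
    if (abs(Tn - T) < tol * diff(rng)) { T <- Tn; break }
    T <- Tn
  }
  T
}

## integer voxel offsets within a physical radius (ellipsoid in index space)
sphereOffsets <- function(radius, voxelSize) {
  rv <- floor(radius / voxelSize)
  g <- expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3])
  d2 <- (g$dz * voxelSize[1])^2 + (g$dy * voxelSize[2])^2 + (g$dx * voxelSize[3])^2
  as.matrix(g[d2 <= radius^2, ])
}

#' Segment the cell body with a sphere probe
#'
#' The fill (biocytin) channel is scanned with a sphere of physical radius
#' `radius` (an ellipsoid in voxel space, respecting anisotropy). A voxel is
#' assigned to the cell body iff at least `fillFrac` of the probe voxels that
#' fall inside the volume are above threshold. The largest 26-connected
#' component of assigned voxels is returned.
#'
#' @param volume fill-channel [VoxelVolume-class].
#' @param radius probe radius, µm (default 0.4, i.e. 10 lateral pixels at the
#'   reference sampling).
#' @param fillFrac required above-threshold fraction of the probe.
#' @param threshold intensity threshold; defaults to [isodataThreshold()] of
#'   the channel.
#' @return a [SomaMask-class].
#' @export
sphereFloodfill <- function(volume, radius = 0.4, fillFrac = 0.40,
                            threshold = NULL) {
  stopifnot1(is(volume, "VoxelVolume"), "volume must be a VoxelVolume")
  vs <- volume@voxelSize
  stopifnot1(radius >= max(vs), "probe radius must be at least one voxel")
  if (is.null(threshold)) threshold <- isodataThreshold(volume)
  bin <- volume@intensities > threshold
  storage.mode(bin) <- "double"
  off <- sphereOffsets(radius, vs)
  counts <- convolveOffsets3d(bin, off)
  norm <- convolveOffsets3d(array(1, dim(bin)), off)
  inside <- counts / pmax(norm, 1) >= fillFrac - 1e-9
  if (!any(inside))
    stop("empty soma: no voxel satisfies the probe criterion", call. = FALSE)
  lab <- cpp_label3d(inside, dim(inside))
  counts <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(counts)
  new("SomaMask", mask = mask, voxelSize = vs,
      surfaceArea = surfaceArea3d(mask, vs), dilationUsed = 0)
}

#' Label marker clusters by 3D flood fill
#'
#' Connected components of the above-threshold voxel set under
#' 26-connectivity; components smaller than `minVoxels` are discarded as
#' noise and surviving labels renumbered densely from 1.
#'
#' @param volume marker-channel [VoxelVolume-class].
#' @param threshold intensity threshold; defaults to [isodataThreshold()].
#' @param minVoxels minimum cluster size, voxels.
#' @return a [ClusterSet-class] (possibly with zero clusters).
#' @export
floodfillClusters <- function(volume, threshold = NULL, minVoxels = 10L) {
  stopifnot1(is(volume, "VoxelVolume"), "volume must be a VoxelVolume")
  if (is.null(threshold)) threshold <- isodataThreshold(volume)
  bin <- volume@intensities > threshold
  lab <- cpp_label3d(bin, dim(bin))
  k <- max(lab)
  if (k > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = k)
    keep <- which(sizes >= minVoxels)
    remap <- integer(k + 1L)
    remap[keep + 1L] <- seq_along(keep)
    lab <- array(remap[lab + 1L], dim(lab))
    sizes <- sizes[keep]
  } else sizes <- integer()
  new("ClusterSet", labels = lab, voxelCounts = as.integer(sizes),
      thresholdUsed = threshold, voxelSize = volume@voxelSize)
}

#' Dilate a soma mask by a physical distance
#'
#' Includes every voxel whose anisotropy-aware Euclidean distance to the mask
#' is at most `distance` (synaptic-cleft compensation). Implemented with an
#' exact separable distance transform in physical units.
#'
#' @param soma a [SomaMask-class].
#' @param distance dilation distance, µm.
#' @return a dilated [SomaMask-class] with `dilationUsed` recorded.
#' @export
dilateSoma <- function(soma, distance) {
  stopifnot1(is(soma, "SomaMask"), "soma must be a SomaMask")
  stopifnot1(distance >= 0, "distance must be >= 0")
  if (distance == 0) return(soma)
  edt <- cpp_edt3d(soma@mask, dim(soma@mask), soma@voxelSize)
  mask <- edt <= distance + 1e-9
  new("SomaMask", mask = mask, voxelSize = soma@voxelSize,
      surfaceArea = surfaceArea3d(mask, soma@voxelSize),
      dilationUsed = soma@dilationUsed + distance)
}

## ------------------------------------------------------------------
## Surface machinery
## ------------------------------------------------------------------

## exposed faces of a mask along the 6 axis directions; returns a list of
## logical arrays named by direction plus the per-face physical areas.
exposedFaces <- function(mask, voxelSize) {
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  areas <- c(voxelSize[2] * voxelSize[3], voxelSize[2] * voxelSize[3],
             voxelSize[1] * voxelSize[3], voxelSize[1] * voxelSize[3],
             voxelSize[1] * voxelSize[2], voxelSize[1] * voxelSize[2])
  faces <- lapply(dirs, function(d)
    mask & !shift3d(mask, -d[1], -d[2], -d[3], fill = FALSE))
  list(faces = faces, areas = areas)
}

## Per-voxel surface-area contribution.
## method "faces": plain exposed-face counting (overestimates oblique
## surfaces by up to sqrt(3)); method "normal": each voxel's face-area sum is
## divided by |n_z| + |n_y| + |n_x| of the local surface normal (gradient of
## the smoothed mask in physical coordinates), which removes the orientation
## bias for smooth surfaces.
.normalWeights <- function(mask, voxelSize) {
  sigmaPhys <- 1.8 * max(voxelSize)
  sm <- gaussBlur3d(array(as.double(mask), dim(mask)), sigmaPhys / voxelSize)
  gz <- (shift3d(sm, -1, 0, 0) - shift3d(sm, 1, 0, 0)) / (2 * voxelSize[1])
  gy <- (shift3d(sm, 0, -1, 0) - shift3d(sm, 0, 1, 0)) / (2 * voxelSize[2])
  gx <- (shift3d(sm, 0, 0, -1) - shift3d(sm, 0, 0, 1)) / (2 * voxelSize[3])
  gn <- sqrt(gz^2 + gy^2 + gx^2)
  w <- (abs(gz) + abs(gy) + abs(gx)) / pmax(gn, 1e-12)
  w[gn < 1e-9] <- 1.5  # degenerate gradient: spherical mean correction
  w
}

surfaceAreaField <- function(mask, voxelSize, method = c("normal", "faces")) {
  method <- match.arg(method)
  ef <- exposedFaces(mask, voxelSize)
  contrib <- array(0, dim(mask))
  for (i in seq_along(ef$faces)) contrib <- contrib + ef$faces[[i]] * ef$areas[i]
  if (method == "faces") return(contrib)
  contrib / .normalWeights(mask, voxelSize)
}

surfaceArea3d <- function(mask, voxelSize, method = "normal") {
  sum(surfaceAreaField(mask, voxelSize, method))
}

## logical array: voxels 26-adjacent to (or coincident with) a cluster voxel
clusterAdjacency <- function(labels) {
  present <- labels > 0L
  adj <- present
  off <- neighbourOffsets(26L)
  for (i in seq_len(nrow(off)))
    adj <- adj | shift3d(present, off$dz[i], off$dy[i], off$dx[i], fill = FALSE)
  adj
}

surfaceMask <- function(mask) {
  surf <- array(FALSE, dim(mask))
  off <- neighbourOffsets(6L)
  for (i in seq_len(nrow(off)))
    surf <- surf | (mask & !shift3d(mask, off$dz[i], off$dy[i], off$dx[i],
                                    fill = FALSE))
  surf
}

#' Optimise the soma dilation against the marker clusters
#'
#' Searches dilation distances on a grid (default 0.16-0.76 µm in one-
#' lateral-voxel steps) and returns the distance maximising the fraction of
#' the dilated soma's surface voxels in contact with marker clusters. Ties —
#' including near-ties within `tieTol` of the maximum, which arise because
#' coverage plateaus once the surface enters an apposed cluster shell —
#' resolve to the smallest distance, so the returned value tracks the cleft
#' width separating the fill and marker signals.
#'
#' @param soma a [SomaMask-class] (undilated).
#' @param clusters a [ClusterSet-class].
#' @param search numeric length-2 search interval, µm.
#' @param step search step, µm.
#' @param tieTol relative coverage tolerance treated as a tie.
#' @return the optimal dilation, µm (with attribute `coverage` giving the
#'   coverage profile over the grid).
#' @export
optimizeDilation <- function(soma, clusters, search = c(0.16, 0.76),
                             step = 0.041, tieTol = 0.02) {
  stopifnot1(is(soma, "SomaMask") && is(clusters, "ClusterSet"),
             "need a SomaMask and a ClusterSet")
  grid <- seq(search[1], search[2], by = step)
  if (!length(clusters@voxelCounts)) {
    warning("no clusters: returning the lower bound", call. = FALSE)
    return(structure(search[1], coverage = setNames(rep(0, length(grid)),
                                                    signif(grid, 3))))
  }
  edt <- cpp_edt3d(soma@mask, dim(soma@mask), soma@voxelSize)
  present <- clusters@labels > 0L
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  ## coverage scored with the same face-contact rule as contactReport
  cov <- vapply(grid, function(d) {
    m <- edt <= d + 1e-9
    nFace <- 0; nHit <- 0
    for (i in 1:6) {
      nbOut <- !shift3d(m, -dirs[i, 1], -dirs[i, 2], -dirs[i, 3], fill = FALSE)
      face <- m & nbOut
      nbClu <- shift3d(present, -dirs[i, 1], -dirs[i, 2], -dirs[i, 3],
                       fill = FALSE)
      nFace <- nFace + sum(face)
      nHit <- nHit + sum(face & (nbClu | present))
    }
    if (nFace == 0) 0 else nHit / nFace
  }, numeric(1))
  if (max(cov) == 0) {
    ## dilation range never reaches the clusters: score by 26-adjacency
    adj <- clusterAdjacency(clusters@labels)
    cov <- vapply(grid, function(d) {
      m <- edt <= d + 1e-9
      surf <- surfaceMask(m)
      ns <- sum(surf)
      if (ns == 0) 0 else sum(surf & adj) / ns
    }, numeric(1))
  }
  best <- grid[which(cov >= (1 - tieTol) * max(cov))[1]]
  structure(best, coverage = setNames(cov, signif(grid, 3)))
}

#' Quantify per-cluster somatic contact areas
#'
#' Exposed faces of the (dilated) soma (faces whose 6-neighbour lies outside
#' the mask) carry the surface area. A face contacts a cluster when the
#' voxel across the face belongs to it, or when the surface voxel itself lies
#' inside the cluster (the usual situation after the optimised dilation
#' places the surface layer within an apposed cluster). Because every face
#' has a unique outside neighbour, contact areas partition the contacted
#' surface and per-cluster areas sum exactly to the total; clusters the
#' surface never reaches this way are scored by 26-adjacency as a fallback so
#' touching-but-not-overlapping geometries still register. Face areas are
#' corrected by the local surface orientation for `areaMethod = "normal"`
#' (see `surfaceAreaField`); `"faces"` reports the raw face-count estimator.
#'
#' @param soma dilated [SomaMask-class].
#' @param clusters [ClusterSet-class].
#' @param areaMethod surface-area estimator.
#' @return a [ContactReport-class].
#' @export
contactReport <- function(soma, clusters, areaMethod = c("normal", "faces")) {
  areaMethod <- match.arg(areaMethod)
  stopifnot1(is(soma, "SomaMask") && is(clusters, "ClusterSet"),
             "need a SomaMask and a ClusterSet")
  if (!any(soma@mask)) stop("empty soma mask", call. = FALSE)
  vs <- soma@voxelSize
  mask <- soma@mask
  labels <- clusters@labels
  k <- length(clusters@voxelCounts)

  ## orientation-correction weights (1 for the raw face-count estimator)
  w <- if (areaMethod == "normal") .normalWeights(mask, vs) else
    array(1, dim(mask))

  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  faceArea <- c(vs[2] * vs[3], vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[3],
                vs[1] * vs[2], vs[1] * vs[2])

  somaSurface <- 0
  perCluster <- rep(0, k)
  touchedAny <- rep(FALSE, k)
  contactedArea <- 0
  for (i in 1:6) {
    dz <- dirs[i, 1]; dy <- dirs[i, 2]; dx <- dirs[i, 3]
    outside <- !shift3d(mask, -dz, -dy, -dx, fill = FALSE)
    face <- mask & outside
    contrib <- faceArea[i] / w[face]
    somaSurface <- somaSurface + sum(contrib)
    if (k > 0) {
      nb <- shift3d(labels, -dz, -dy, -dx, fill = 0L)
      lab <- nb[face]
      own <- labels[face]
      lab[lab == 0L] <- own[lab == 0L]
      sel <- lab > 0L
      if (any(sel)) {
        sums <- rowsum(contrib[sel], lab[sel])
        ids <- as.integer(rownames(sums))
        perCluster[ids] <- perCluster[ids] + sums[, 1]
        touchedAny[ids] <- TRUE
        contactedArea <- contactedArea + sum(contrib[sel])
      }
    }
  }

  ## fallback: clusters never met face-on score by 26-adjacency of surface
  ## voxels (rim-style, used only for clusters the dilation never reached)
  if (k > 0 && any(!touchedAny)) {
    missing <- which(!touchedAny)
    msel <- array(0L, dim(labels))
    mk <- array(labels %in% missing, dim(labels))
    msel[mk] <- labels[mk]
    surf <- surfaceMask(mask)
    field <- surfaceAreaField(mask, vs, areaMethod)
    offs <- as.matrix(neighbourOffsets(26L))
    assigned <- array(0L, dim(mask))
    for (i in seq_len(nrow(offs))) {
      L <- shift3d(msel, offs[i, 1], offs[i, 2], offs[i, 3], fill = 0L)
      fresh <- surf & L > 0L & assigned == 0L
      assigned[fresh] <- L[fresh]
    }
    for (lbl in missing) {
      sel <- assigned == lbl
      perCluster[lbl] <- sum(field[sel])
      contactedArea <- contactedArea + perCluster[lbl]
    }
  }

  total <- sum(perCluster)
  ord <- order(-perCluster, -clusters@voxelCounts, seq_len(max(k, 1)))
  largest <- if (k >= 1) perCluster[ord[1]] else 0
  second <- if (k >= 2) perCluster[ord[2]] else 0
  new("ContactReport",
      clusterArea = perCluster, totalContactArea = total,
      somaSurfaceArea = somaSurface,
      coverageFraction = min(1, if (somaSurface > 0) total / somaSurface else 0),
      largestArea = largest, secondLargestArea = second,
      contactRatio = if (total > 0) largest / total else NA_real_,
      metadata = list(dilation = soma@dilationUsed, areaMethod = areaMethod,
                      nClusters = k))
}

#' Segment one cell's volumes end to end
#'
#' IsoData-thresholds both channels, segments the soma with the sphere probe,
#' labels the marker clusters, optimises the dilation and returns the contact
#' report. An optional exclusion mask (e.g. manually flagged axonal fill
#' signal) is removed from the fill channel before segmentation.
#'
#' @param fill,marker [VoxelVolume-class] channels.
#' @param exclusionMask optional logical array matching the fill channel.
#' @param probeRadius,fillFrac sphere-probe parameters.
#' @param minVoxels minimum cluster size.
#' @param search,step dilation search grid, µm.
#' @param areaMethod surface-area estimator (see [contactReport()]).
#' @return list with `soma` (dilated), `clusters`, `dilation`, `report`.
#' @export
segmentCell <- function(fill, marker, exclusionMask = NULL,
                        probeRadius = 0.4, fillFrac = 0.40, minVoxels = 10L,
                        search = c(0.16, 0.76), step = 0.041,
                        areaMethod = "normal") {
  if (!is.null(exclusionMask)) {
    stopifnot1(all(dim(exclusionMask) == dim(fill@intensities)),
               "exclusion mask must match the fill channel")
    ints <- fill@intensities
    ints[exclusionMask] <- min(ints)
    fill <- new("VoxelVolume", intensities = ints, voxelSize = fill@voxelSize,
                channelName = fill@channelName)
  }
  soma <- sphereFloodfill(fill, radius = probeRadius, fillFrac = fillFrac)
  clusters <- floodfillClusters(marker, minVoxels = minVoxels)
  d <- optimizeDilation(soma, clusters, search = search, step = step)
  dil <- dilateSoma(soma, as.numeric(d))
  rep <- contactReport(dil, clusters, areaMethod = areaMethod)
  list(soma = dil, clusters = clusters, dilation = as.numeric(d), report = rep)
}
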