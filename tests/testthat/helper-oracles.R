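## Independent brute-force oracles and small ground-truth builders used
## across the suite. These deliberately do not reuse the package's internal
## helpers.

## construct a cell with fully specified inputs
makeTestCell <- function(rors, lats = NULL, thresholds = NULL, actP = 1,
                         trialCV = 0.001, latCV = 0.001, calyceal = FALSE,
                         preAmp = 0.3, soma = 4, age = 5,
                         beta = 6.8, alpha = 0.35) {
  n <- length(rors)
  if (is.null(lats)) lats <- seq(2, by = 1.4, length.out = n)
  if (is.null(thresholds)) thresholds <- seq(0.10, 0.38, length.out = n)
  inputs <- data.frame(
    true_ror = rors, dev_ror = rors,
    recruitment_threshold = thresholds,
    activation_prob = rep(actP, n)[seq_len(n)],
    latency_mean = lats,
    latency_cv = rep(latCV, n)[seq_len(n)],
    is_calyceal = seq_len(n) == 1 & calyceal,
    prespike_amp = ifelse(seq_len(n) == 1 & calyceal, preAmp, 0),
    ror_trial_cv = rep(trialCV, n)[seq_len(n)])
  new("CellGroundTruth", age = age, inputs = inputs,
      trueContactAreas = (rors / beta)^(1 / alpha), somaRadius = soma)
}

## independent array shift (zero/FALSE/Inf fill), used only by the oracles
oShift <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  zs <- max(1, 1 + off[1]):min(d[1], d[1] + off[1])
  ys <- max(1, 1 + off[2]):min(d[2], d[2] + off[2])
  xs <- max(1, 1 + off[3]):min(d[3], d[3] + off[3])
  if (!length(zs) || !length(ys) || !length(xs)) return(out)
  out[zs, ys, xs] <- a[zs - off[1], ys - off[2], xs - off[3]]
  out
}

## reference 26-connected labelling via an independent graph library:
## voxels are vertices, 26-neighbour pairs are edges, clusters are graph
## components; components renumbered densely in scan order of their first
## voxel (the canonical order a scan-order flood fill produces)
bruteLabel3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  out <- array(0L, d)
  if (!length(idx)) return(out)
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dz = c(0, 1), dy = -1:1, dx = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), , drop = FALSE]
  offs <- offs[offs[, 1] == 1 | (offs[, 1] == 0 & (offs[, 2] == 1 |
               (offs[, 2] == 0 & offs[, 3] == 1))), , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    nb <- oShift(vid, offs[i, ], 0L)
    sel <- which(vid > 0L & nb > 0L)
    if (length(sel))
      edges[[length(edges) + 1L]] <- cbind(vid[sel], nb[sel])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - max(0L, length(igraph::V(g)))))
  memb <- igraph::components(g)$membership
  ## renumber densely by first appearance in scan order
  remap <- integer(max(memb))
  nxt <- 0L
  lab <- integer(length(idx))
  for (q in seq_along(idx)) {
    m <- memb[q]
    if (remap[m] == 0L) { nxt <- nxt + 1L; remap[m] <- nxt }
    lab[q] <- remap[m]
  }
  out[idx] <- lab
  out
}

## brute-force anisotropic EDT on small grids
bruteEDT <- function(mask, spacing) {
  d <- dim(mask)
  idx <- which(mask)
  stopifnot(length(idx) > 0)
  mi <- arrayInd(idx, d)
  out <- array(NA_real_, d)
  all <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(prod(d))) {
    dd <- (spacing[1] * (all[v, 1] - mi[, 1]))^2 +
      (spacing[2] * (all[v, 2] - mi[, 2]))^2 +
      (spacing[3] * (all[v, 3] - mi[, 3]))^2
    out[v] <- sqrt(min(dd))
  }
  out
}

## exhaustive intermeans fixed-point search: returns every threshold value T*
## with T* = (mean(x <= T*) + mean(x > T*)) / 2 consistent with its own
## partition
isodataFixedPoints <- function(x) {
  sx <- sort(unique(x))
  out <- numeric()
  for (k in seq_len(length(sx) - 1)) {
    lo <- x <= sx[k]
    g <- (mean(x[lo]) + mean(x[!lo])) / 2
    if (g >= sx[k] && g < sx[k + 1]) out <- c(out, g)
  }
  out
}
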