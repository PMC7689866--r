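## Internal helpers shared across modules.

## Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
## caller's state afterwards. All stochastic operations funnel through this so
## identical (params, seed) give bit-identical output.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot1 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

oddWindow <- function(n) if (n %% 2L == 0L) n + 1L else n

## Savitzky-Golay m-th derivative of a sampled voltage trace.
## v in mV, fs in Hz; returns mV/ms^m (so the first derivative is in V/s).
sgDerivative <- function(v, fs, m = 1L, p = 3L, windowMs = 0.24) {
  n <- oddWindow(max(p + 2L, as.integer(round(windowMs * fs / 1000)) + 1L))
  if (n / fs > 7e-4)
    stop("sampling rate too low to resolve the ", windowMs,
         " ms smoothing window", call. = FALSE)
  if (length(v) < n) return(rep(0, length(v)))
  signal::sgolayfilt(v, p = p, n = n, m = m, ts = 1000 / fs)
}

## Truncated normal draw (lower bound only), by rejection with a fallback clamp.
rnormTrunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
    tries <- tries + 1L
  }
  x[x < lower] <- lower
  x
}

## ---- 3D array helpers (arrays are ZYX: dim = c(nz, ny, nx)) ----

## Shift a 3D array by integer offsets, zero-filling (FALSE/0) at borders.
shift3d <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  off <- c(dz, dy, dx)
  dstIdx <- srcIdx <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) {
      dstIdx[[k]] <- seq.int(1 + o, d[k])
      srcIdx[[k]] <- seq.int(1, d[k] - o)
    } else {
      dstIdx[[k]] <- seq.int(1, d[k] + o)
      srcIdx[[k]] <- seq.int(1 - o, d[k])
    }
    if (length(dstIdx[[k]]) == 0) return(out)
  }
  out[dstIdx[[1]], dstIdx[[2]], dstIdx[[3]]] <-
    a[srcIdx[[1]], srcIdx[[2]], srcIdx[[3]]]
  out
}

neighbourOffsets <- function(connectivity = 26L) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dz) + abs(g$dy) + abs(g$dx) == 1, ]
  g
}

## Circular FFT convolution of a 3D array with a small kernel given as a
## matrix of integer offsets (rows: dz,dy,dx). Returns, per voxel, the sum of
## `a` over the offset neighbourhood (within-volume part only, via padding).
convolveOffsets3d <- function(a, offsets) {
  d <- dim(a)
  pad <- c(max(abs(offsets[, 1])), max(abs(offsets[, 2])), max(abs(offsets[, 3])))
  dp <- d + 2 * pad
  big <- array(0, dp)
  big[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <- a
  ker <- array(0, dp)
  idx <- cbind((offsets[, 1]) %% dp[1] + 1L,
               (offsets[, 2]) %% dp[2] + 1L,
               (offsets[, 3]) %% dp[3] + 1L)
  for (i in seq_len(nrow(idx))) ker[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      ker[idx[i, 1], idx[i, 2], idx[i, 3]] + 1
  res <- Re(fft(fft(big) * Conj(fft(ker)), inverse = TRUE)) / prod(dp)
  res[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])]
}

## Gaussian blur of a 3D array via FFT (circular; fine for dark-bordered
## volumes). sigma given per dimension in voxels.
gaussBlur3d <- function(a, sigmaVox) {
  if (all(sigmaVox <= 0)) return(a)
  d <- dim(a)
  kern1 <- function(n, s) {
    if (s <= 0) { k <- numeric(n); k[1] <- 1; return(k) }
    off <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-off^2 / (2 * s^2))
    k / sum(k)
  }
  Fz <- fft(kern1(d[1], sigmaVox[1]))
  Fy <- fft(kern1(d[2], sigmaVox[2]))
  Fx <- fft(kern1(d[3], sigmaVox[3]))
  transfer <- array(outer(outer(Fz, Fy), Fx), d)
  Re(fft(fft(a) * transfer, inverse = TRUE)) / prod(d)
}
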