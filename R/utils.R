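# Internal numerical helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user simulations.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# 1D convolution along the rows of a matrix with reflected boundaries.
convolveRows <- function(m, k) {
  n <- nrow(m)
  half <- (length(k) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k)) {
    src <- seq_len(n) + (t - half - 1L)
    src[src < 1L] <- 2L - src[src < 1L]
    src[src > n] <- 2L * n - src[src > n]
    out <- out + k[t] * m[src, , drop = FALSE]
  }
  out
}

gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array; sigma per dimension, in voxels.
gaussSmooth3d <- function(a, sigma = c(1, 1, 1)) {
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gaussKernel(sigma[ax])
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- array(convolveRows(matrix(ap, dp[1L]), k), dp)
    a <- aperm(ap, order(perm))
  }
  a
}

gaussSmooth2d <- function(m, sigma = 1) {
  k <- gaussKernel(sigma)
  t(convolveRows(t(convolveRows(m, k)), k))
}

# Median filter of a matrix with an odd square window, reflected boundaries.
medianFilter2d <- function(m, size = 5L) {
  stopifnot(size %% 2L == 1L)
  half <- (size - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  refl <- function(i, len) {
    i[i < 1L] <- 2L - i[i < 1L]
    i[i > len] <- 2L * len - i[i > len]
    i
  }
  stackv <- matrix(0, n * p, size * size)
  t <- 0L
  for (dx in -half:half) for (dy in -half:half) {
    t <- t + 1L
    stackv[, t] <- m[refl(seq_len(n) + dx, n), refl(seq_len(p) + dy, p)]
  }
  matrix(apply(stackv, 1L, stats::median), n, p)
}

# Otsu threshold on a vector of non-negative values: maximizes between-class
# variance of the binarization over a fixed number of histogram levels.
# Returns the threshold value (mask = values > threshold).
otsuThreshold <- function(x, levels = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[levels]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  mids[which.max(sigmaB)]
}

# Integer voxel offsets of an anisotropic ball of physical radius rUm.
ballOffsets <- function(rUm, pixelSizeUm, zStepUm) {
  rx <- floor(rUm / pixelSizeUm)
  rz <- floor(rUm / zStepUm)
  g <- expand.grid(dx = -rx:rx, dy = -rx:rx, dz = -rz:rz)
  keep <- (g$dx * pixelSizeUm)^2 + (g$dy * pixelSizeUm)^2 +
    (g$dz * zStepUm)^2 <= rUm^2
  as.matrix(g[keep, , drop = FALSE])
}

# Dilate a set of voxel coordinates (n x 3 matrix) by a set of offsets and
# mark them TRUE in a logical array of dims `d`. Out-of-bounds voxels dropped.
paintDilated <- function(mask, coords, offsets) {
  d <- dim(mask)
  for (t in seq_len(nrow(offsets))) {
    p <- coords
    p[, 1] <- p[, 1] + offsets[t, 1]
    p[, 2] <- p[, 2] + offsets[t, 2]
    p[, 3] <- p[, 3] + offsets[t, 3]
    ok <- p[, 1] >= 1L & p[, 1] <= d[1] & p[, 2] >= 1L & p[, 2] <= d[2] &
      p[, 3] >= 1L & p[, 3] <= d[3]
    if (any(ok))
      mask[p[ok, , drop = FALSE]] <- TRUE
  }
  mask
}

# Dilate a logical 3D mask by a physical radius (used for the optional
# imbrication tolerance dilation).
dilateMask3d <- function(mask, rUm, pixelSizeUm, zStepUm) {
  if (rUm <= 0) return(mask)
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(mask)
  paintDilated(mask, coords, ballOffsets(rUm, pixelSizeUm, zStepUm))
}

# Fraction of a shifted mono-exponential decay falling in each temporal bin.
# The decay rises at `peakNs` and decays with lifetime `tauNs`; bins are
# [ (c-1) w, c w ) for c = 1..n. Fractions are normalized to sum to 1.
flimChannelFractions <- function(tauNs, peakNs = 1.33, widthNs = 2.08,
                                 n = 4L) {
  lo <- (seq_len(n) - 1) * widthNs
  hi <- lo + widthNs
  a <- pmax(lo, peakNs)
  f <- ifelse(hi > peakNs,
              exp(-(a - peakNs) / tauNs) - exp(-(hi - peakNs) / tauNs), 0)
  f / sum(f)
}

# Depth (um) of each acquired plane, plane 1 at depth 0.
planeDepths <- function(nz, zStepUm) (seq_len(nz) - 1) * zStepUm

# Total temporally-integrated 2PEF volume and SHG volume of a stack.
totalPef <- function(stack) {
  ints <- stack@intensities
  tc <- seq_len(stack@meta@nTimeChannels)
  out <- ints[, , , tc[1L]]
  for (c in tc[-1L]) out <- out + ints[, , , c]
  out
}

shgVolume <- function(stack) {
  stack@intensities[, , , stack@meta@shgChannelIndex]
}

# Expand a (nx x ny) map to (nx x ny x nz).
repMap <- function(m, nz) array(m, c(dim(m), nz))

# 3D array of plane depths broadcast over (nx, ny, nz).
depthVolume <- function(dims, zStepUm) {
  array(rep(planeDepths(dims[3L], zStepUm), each = dims[1L] * dims[2L]), dims)
}
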