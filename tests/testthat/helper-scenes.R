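# Shared scene builders for the test suite. All randomness is seeded
# through SceneParams or withr::with_seed so every test is reproducible.

noiselessParams <- function(...) {
  SceneParams(gaussianSd = 0, poissonScale = 0, ...)
}

# A minimal CellRecord wrapping an arbitrary filled mask (no nucleus),
# for exercising partitioning on shapes the generator does not produce.
maskCellRecord <- function(mask, pixelSizeUm = 0.212, cellId = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  new("CellRecord", cellId = as.integer(cellId), bodyMask = mask,
      nucleusMask = matrix(FALSE, nrow(mask), ncol(mask)),
      filledMask = mask, centroid = c(mean(idx[, 1]), mean(idx[, 2])),
      boundary = matrix(numeric(0), 0L, 2L),
      areaUm2 = sum(mask) * pixelSizeUm^2, expressionMean = NA_real_,
      pixelSizeUm = pixelSizeUm, flags = character())
}

# Random smooth blob mask on an n x n grid (perturbed disk, analytic).
randomBlobMask <- function(n = 64L, seed = 1L) {
  withr::with_seed(seed, {
    ctr <- runif(2, n * 0.4, n * 0.6)
    R0 <- runif(1, n * 0.12, n * 0.28)
    w <- abs(rnorm(3)); w <- w / sum(w) * runif(1, 0, 0.25)
    ph <- runif(3, 0, 2 * pi)
    rowg <- matrix(seq_len(n), n, n)
    colg <- matrix(seq_len(n), n, n, byrow = TRUE)
    phi <- atan2(rowg - ctr[1], colg - ctr[2])
    rad <- sqrt((rowg - ctr[1])^2 + (colg - ctr[2])^2)
    R <- R0 * (1 + w[1] * cos(2 * phi + ph[1]) + w[2] * cos(3 * phi + ph[2]) +
                 w[3] * cos(4 * phi + ph[3]))
    rad <= R
  })
}

# O(fg x bg) exhaustive Euclidean distance from each foreground pixel to
# the nearest background pixel -- the independent oracle for the band
# partition.
bruteForceBoundaryDistance <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  d2 <- outer(fg[, 1], bg[, 1], `-`)^2 + outer(fg[, 2], bg[, 2], `-`)^2
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  out[mask] <- sqrt(apply(d2, 1L, min))
  out
}

# Ratio computed by brute-force per-pixel averaging over arbitrary masks.
bruteForceRatio <- function(px, bandMask, cytoMask) {
  mean(px[bandMask]) / mean(px[cytoMask])
}
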