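#' Pixel-wise cytofluorogram of two channels
#'
#' Pairs all in-mask pixels of two aligned channels and computes their
#' Pearson correlation coefficient r, the standard read-out of pixel-wise
#' colocalization for a field of cells (or a single cell). A 2-D histogram
#' of the pairs is available via [cytofluorogramHistogram].
#'
#' @param chA,chB [Micrograph-class] objects on the same geometry.
#' @param mask logical matrix selecting the pixels to pair (e.g. the union
#'   of cell masks of the field).
#' @param provenance `"field"` or `"cell"`, recorded on the result.
#' @return a [Cytofluorogram-class]; masks under 100 pixels are flagged
#'   `"small_mask"` (unstable r).
#' @examples
#' sc <- makeTwoChannelScene(SceneParams(seed = 2), rho = 0.8)
#' cyto <- cytofluorogram(sc$chA, sc$chB, sc$truth@cells[[1]]$filledMask)
#' cyto@r
#' @export
cytofluorogram <- function(chA, chB, mask, provenance = "field") {
  stopIfNot(is(chA, "Micrograph") && is(chB, "Micrograph"),
            "chA and chB must be Micrographs")
  stopIfNot(identical(dim(chA@pixels), dim(chB@pixels)) &&
              identical(dim(chA@pixels), dim(mask)),
            "channels and mask must share one geometry")
  stopIfNot(any(mask), "empty mask")
  a <- chA@pixels[mask]
  b <- chB@pixels[mask]
  stopIfNot(length(a) >= 2L, "need at least two in-mask pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: a channel is constant within the mask",
         call. = FALSE)
  flags <- if (length(a) < 100L) "small_mask" else character()
  new("Cytofluorogram", a = a, b = b, r = stats::cor(a, b),
      n = length(a), provenance = provenance, flags = flags)
}

#' 2-D histogram of a cytofluorogram
#'
#' @param x a [Cytofluorogram-class].
#' @param nbins bins per axis.
#' @return long-format data.frame (a_mid, b_mid, count).
#' @export
cytofluorogramHistogram <- function(x, nbins = 64L) {
  ab <- range(x@a)
  bb <- range(x@b)
  ea <- seq(ab[[1L]], ab[[2L]], length.out = nbins + 1L)
  eb <- seq(bb[[1L]], bb[[2L]], length.out = nbins + 1L)
  ia <- findInterval(x@a, ea, rightmost.closed = TRUE)
  ib <- findInterval(x@b, eb, rightmost.closed = TRUE)
  tab <- table(factor(ia, seq_len(nbins)), factor(ib, seq_len(nbins)))
  data.frame(a_mid = rep((ea[-1L] + ea[-(nbins + 1L)]) / 2, nbins),
             b_mid = rep((eb[-1L] + eb[-(nbins + 1L)]) / 2, each = nbins),
             count = as.vector(tab))
}

#' Extract an intensity linescan
#'
#' Samples the image by bilinear interpolation at one-pixel spacing along
#' the segment from `p0` to `p1`, averaging `widthPx` parallel samples
#' taken perpendicular to the line. On axis-aligned lines with width 1 the
#' raster values are returned exactly.
#'
#' @param img a [Micrograph-class].
#' @param p0,p1 segment endpoints, `c(row, col)` in pixels.
#' @param widthPx number of perpendicular samples averaged (>= 1).
#' @return data.frame (position_um, intensity) with attributes `p0`, `p1`,
#'   `width_px`.
#' @export
extractLinescan <- function(img, p0, p1, widthPx = 1L) {
  stopIfNot(is(img, "Micrograph"), "img must be a Micrograph")
  stopIfNot(widthPx >= 1L, "widthPx must be >= 1")
  d <- dim(img@pixels)
  for (p in list(p0, p1))
    stopIfNot(length(p) == 2L && p[[1L]] >= 1 && p[[1L]] <= d[[1L]] &&
                p[[2L]] >= 1 && p[[2L]] <= d[[2L]],
              "endpoints must lie inside the image")
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  stopIfNot(len > 0, "zero-length line")
  u <- v / len
  perp <- c(-u[[2L]], u[[1L]])
  t <- seq(0, len, by = 1)
  offs <- seq_len(widthPx) - (widthPx + 1) / 2
  acc <- 0
  for (o in offs)
    acc <- acc + bilinearInterp(img@pixels,
                                p0[[1L]] + t * u[[1L]] + o * perp[[1L]],
                                p0[[2L]] + t * u[[2L]] + o * perp[[2L]])
  out <- data.frame(position_um = t * img@pixelSizeUm,
                    intensity = acc / widthPx)
  attr(out, "p0") <- p0
  attr(out, "p1") <- p1
  attr(out, "width_px") <- widthPx
  out
}

#' Intensity profile along the longest cell axis
#'
#' Finds the principal axis of the filled body mask (eigenvector of the
#' pixel-coordinate covariance), draws a line through the centroid along
#' it, clipped to the mask extent plus `marginUm`, and extracts the
#' profile. Near-circular cells (axis-length ratio < 1.05) are flagged via
#' the `"flags"` attribute; any diameter is then as good as another.
#'
#' @param img a [Micrograph-class].
#' @param cell a [CellRecord-class].
#' @param widthPx perpendicular averaging width.
#' @param marginUm extension beyond the mask extent at both ends (um).
#' @return a linescan data.frame as from [extractLinescan], plus
#'   attributes `axis_angle_rad` and `flags`.
#' @export
longestAxisProfile <- function(img, cell, widthPx = 1L, marginUm = 1) {
  idx <- which(cell@filledMask, arr.ind = TRUE)
  stopIfNot(nrow(idx) >= 3L, "degenerate mask")
  cv <- stats::cov(idx)
  eg <- eigen(cv, symmetric = TRUE)
  u <- eg$vectors[, 1L] # (drow, dcol) of the major axis
  flags <- if (sqrt(eg$values[[1L]] / max(eg$values[[2L]], 1e-12)) < 1.05)
    "near_circular" else character()
  ctr <- cell@centroid
  proj <- (idx[, 1L] - ctr[[1L]]) * u[[1L]] + (idx[, 2L] - ctr[[2L]]) * u[[2L]]
  mpx <- marginUm / img@pixelSizeUm
  d <- dim(img@pixels)
  clip <- function(p) c(min(max(p[[1L]], 1), d[[1L]]),
                        min(max(p[[2L]], 1), d[[2L]]))
  p0 <- clip(ctr + (min(proj) - mpx) * u)
  p1 <- clip(ctr + (max(proj) + mpx) * u)
  out <- extractLinescan(img, p0, p1, widthPx)
  attr(out, "axis_angle_rad") <- atan2(u[[1L]], u[[2L]])
  attr(out, "flags") <- flags
  out
}

#' Normalize an intensity profile to [0, 1]
#'
#' `(I - min) / (max - min)`; idempotent, order-preserving, errors on a
#' constant profile.
#'
#' @param profile data.frame with an `intensity` column (or numeric
#'   vector).
#' @return the profile with intensity rescaled so its minimum is 0 and
#'   maximum is 1.
#' @examples
#' normalizeProfile(c(2, 4, 6))
#' @export
normalizeProfile <- function(profile) {
  vec <- !is.data.frame(profile)
  y <- if (vec) profile else profile$intensity
  rg <- range(y)
  stopIfNot(rg[[2L]] > rg[[1L]], "constant profile cannot be normalized")
  y <- (y - rg[[1L]]) / (rg[[2L]] - rg[[1L]])
  if (vec) return(y)
  profile$intensity <- y
  profile
}

# Harrell's standard knot-placement quantiles for restricted cubic splines.
rcsKnotQuantiles <- function(nKnots) {
  switch(as.character(nKnots),
         "3" = c(.10, .50, .90),
         "4" = c(.05, .35, .65, .95),
         "5" = c(.05, .275, .50, .725, .95),
         "6" = c(.05, .23, .41, .59, .77, .95),
         "7" = c(.025, .1833, .3417, .50, .6583, .8167, .975),
         seq(.05, .95, length.out = nKnots))
}

#' Average normalized profiles with a restricted cubic spline
#'
#' Pools the points of all profiles and fits a restricted cubic spline
#' (natural cubic basis, linear beyond the boundary knots, knots at the
#' standard quantiles of the pooled positions) by least squares; the fitted
#' curve on a common grid is the mean curve. SD and SEM bands are computed
#' pointwise from the individual profiles interpolated to the grid
#' (`SEM = SD / sqrt(n)`), matching the usual shaded-band semantics.
#'
#' @param profiles list of >= 2 data.frames (position_um, intensity),
#'   typically normalized with [normalizeProfile]; position ranges must
#'   overlap.
#' @param nKnots number of knots (>= 3), default 5.
#' @param grid common position grid; default 100 points spanning the
#'   overlap of all profiles.
#' @return object of class `"SplineSummary"`: list with `grid`, `mean`,
#'   `sd`, `sem`, `n`, `knots`.
#' @export
averageProfilesSpline <- function(profiles, nKnots = 5L, grid = NULL) {
  stopIfNot(is.list(profiles) && length(profiles) >= 2L,
            "need at least two profiles")
  stopIfNot(nKnots >= 3L, "nKnots must be >= 3")
  lo <- max(vapply(profiles, function(p) min(p$position_um), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$position_um), numeric(1)))
  stopIfNot(hi > lo, "profile position ranges do not overlap")
  if (is.null(grid)) grid <- seq(lo, hi, length.out = 100L)

  x <- unlist(lapply(profiles, function(p) p$position_um))
  y <- unlist(lapply(profiles, function(p) p$intensity))
  kq <- rcsKnotQuantiles(nKnots)
  knots <- unique(stats::quantile(x, kq, names = FALSE))
  stopIfNot(length(knots) >= 3L, "degenerate knot set")
  inner <- knots[-c(1L, length(knots))]
  bnd <- knots[c(1L, length(knots))]
  basis <- splines::ns(x, knots = inner, Boundary.knots = bnd)
  fit <- stats::lm.fit(cbind(1, basis), y)
  gb <- splines::ns(grid, knots = inner, Boundary.knots = bnd)
  meanCurve <- as.vector(cbind(1, gb) %*% fit$coefficients)

  interp <- vapply(profiles, function(p)
    stats::approx(p$position_um, p$intensity, xout = grid, rule = 2)$y,
    numeric(length(grid)))
  interp <- matrix(interp, nrow = length(grid))
  # a least-squares spline can overshoot near the boundary knots by a
  # fraction of the noise; the averaged curve is kept inside the pointwise
  # data envelope
  meanCurve <- pmin(pmax(meanCurve, apply(interp, 1L, min)),
                    apply(interp, 1L, max))
  sdBand <- apply(interp, 1L, stats::sd)
  structure(list(grid = grid, mean = meanCurve, sd = sdBand,
                 sem = sdBand / sqrt(length(profiles)),
                 n = length(profiles), knots = knots),
            class = "SplineSummary")
}

#' @export
print.SplineSummary <- function(x, ...) {
  cat(sprintf(
    "SplineSummary: %d profiles on %d grid points, %d knots [%.2f..%.2f um]\n",
    x$n, length(x$grid), length(x$knots), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Correlation of paired two-channel pseudopod profiles
#'
#' For paired linescans of the same lines in two channels (e.g. a myosin
#' and an actin reporter during leading-edge extension), computes the
#' per-line Pearson correlation of the normalized profiles and the
#' spline-averaged mean curves of both channels.
#'
#' @param profilesA,profilesB lists of paired data.frames
#'   (position_um, intensity); element i of each list comes from the same
#'   line.
#' @param nKnots spline knots for the averaged curves.
#' @return list: `perLineR`, `meanR`, `splineA`, `splineB`.
#' @export
pseudopodCostainingCorrelation <- function(profilesA, profilesB,
                                           nKnots = 5L) {
  stopIfNot(length(profilesA) == length(profilesB) && length(profilesA) >= 1L,
            "profilesA and profilesB must be paired, non-empty lists")
  nA <- lapply(profilesA, normalizeProfile)
  nB <- lapply(profilesB, normalizeProfile)
  perLineR <- vapply(seq_along(nA), function(i) {
    a <- nA[[i]]
    b <- nB[[i]]
    bi <- stats::approx(b$position_um, b$intensity, xout = a$position_um,
                        rule = 2)$y
    stats::cor(a$intensity, bi)
  }, numeric(1))
  list(perLineR = perLineR, meanR = mean(perLineR),
       splineA = if (length(nA) >= 2L) averageProfilesSpline(nA, nKnots),
       splineB = if (length(nB) >= 2L) averageProfilesSpline(nB, nKnots))
}
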