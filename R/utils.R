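#' Bilinear interpolation on an intensity matrix
#'
#' Samples `px` at fractional (row, col) positions. Coordinates are clamped
#' to the image extent; at exact integer coordinates the raster value is
#' returned without interpolation error.
#'
#' @param px numeric matrix of intensities.
#' @param r,c numeric vectors of fractional row/column positions (1-based,
#'   pixel centers).
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinearInterp <- function(px, r, c) {
  nr <- nrow(px)
  nc <- ncol(px)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    px[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    px[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    px[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Strip the EBImage Image class, returning a plain base matrix.
asPlainMatrix <- function(x) {
  m <- EBImage::imageData(x)
  matrix(as.vector(m), nrow = dim(m)[[1L]], ncol = dim(m)[[2L]])
}

# Exact Euclidean distance of every foreground pixel to the nearest
# background pixel (pixel units). Thin wrapper so the choice of engine is a
# single point of change.
distanceToBackground <- function(mask) {
  storage.mode(mask) <- "double"
  asPlainMatrix(EBImage::distmap(EBImage::Image(mask)))
}

# Pixel-unit distance threshold for a band of physical width wUm. The
# distance transform measures to the nearest background pixel *center*,
# which overestimates the distance to the continuous cell boundary by
# between 0 and ~0.5 px depending on the sub-pixel boundary position and
# whether the nearest background center lies on- or off-normal; for an
# isotropic boundary the mean overestimate is close to a quarter pixel
# (verified against analytic annuli of ideal disks over a range of radii
# and pixel sizes). Without the offset a digital band is systematically
# thinner than its nominal width by ~7%.
bandDistanceThreshold <- function(wUm, pixelSizeUm) {
  wUm / pixelSizeUm + 0.25
}

# Run-length encode a logical mask (column-major) for JSON export.
maskToRLE <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

rleToMask <- function(x) {
  v <- inverse.rle(structure(list(lengths = x$lengths,
                                  values = as.logical(x$values)),
                             class = "rle"))
  matrix(v, nrow = x$dim[[1]], ncol = x$dim[[2]])
}

# Angular position of pixels about a centroid: measured from the +x axis
# (increasing column) toward +y (increasing row), in (-pi, pi]. One fixed
# convention used by the renderer, the asymmetry bins and the ray caster.
pixelAngle <- function(row, col, centroid) {
  atan2(row - centroid[[1]], col - centroid[[2]])
}

# Circular difference in radians, result in [0, pi].
angleDiff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Deterministic child seeds derived from a master seed (31-bit range).
childSeeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Deterministic md5 of an R object (used for run manifests).
objectHash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
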