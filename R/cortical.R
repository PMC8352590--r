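#' Cortex-to-cytoplasm intensity ratio
#'
#' Mean intensity over the cortical band divided by mean intensity over the
#' cytoplasm (nucleus excluded). Values above 1 indicate cortical
#' enrichment; the ratio is invariant to global intensity rescaling.
#'
#' @param img a [Micrograph-class].
#' @param part a [CorticalPartition-class] on the same geometry.
#' @return the ratio (numeric), or `NA` with a warning when the partition
#'   is flagged unmeasurable.
#' @examples
#' sc <- makeCellScene(SceneParams(enrichment = 1.5, gaussianSd = 0,
#'                                 poissonScale = 0))
#' img <- maxProject(sc$stack)
#' cell <- segmentCells(img)[[1]]
#' cortexCytoRatio(img, partitionCortex(cell))
#' @export
cortexCytoRatio <- function(img, part) {
  stopIfNot(is(img, "Micrograph") && is(part, "CorticalPartition"),
            "need a Micrograph and a CorticalPartition")
  if ("unmeasurable" %in% part@flags || !any(part@cytoplasmMask)) {
    warning("cell flagged unmeasurable: no cytoplasm left outside the band",
            call. = FALSE)
    return(NA_real_)
  }
  stopIfNot(any(part@bandMask), "empty cortical band")
  cyto <- mean(img@pixels[part@cytoplasmMask])
  stopIfNot(cyto > 0, "zero cytoplasm mean: ratio undefined")
  mean(img@pixels[part@bandMask]) / cyto
}

binBandPixels <- function(img, part, cell, nBins) {
  idx <- which(part@bandMask, arr.ind = TRUE)
  ang <- pixelAngle(idx[, 1L], idx[, 2L], cell@centroid)
  edges <- seq(-pi, pi, length.out = nBins + 1L)
  bin <- findInterval(ang, edges, rightmost.closed = TRUE)
  vals <- img@pixels[part@bandMask]
  means <- vapply(seq_len(nBins), function(b) {
    v <- vals[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  counts <- tabulate(bin, nBins)
  data.frame(bin = seq_len(nBins),
             angle_rad = (edges[-1L] + edges[-(nBins + 1L)]) / 2,
             mean_intensity = means, n_pixels = counts)
}

#' Cortical asymmetry (peripheral intensity SD)
#'
#' Assigns cortical-band pixels to `nBins` angular bins about the cell
#' centroid, averages intensity per bin, and reports the standard deviation
#' across bin means. A uniform cortical signal gives an SD near zero; a
#' polarized (leading-edge) signal gives a high SD. Empty bins (concave
#' outlines) are excluded; when more than 25% of bins are empty the result
#' carries the flag `"concave"`.
#'
#' @param img a [Micrograph-class].
#' @param part a [CorticalPartition-class].
#' @param cell the [CellRecord-class] providing the centroid.
#' @param nBins number of angular bins (>= 8), default 360.
#' @param mode `"bin_means"` (default; SD across angular-bin means,
#'   independent of band thickness) or `"pixels"` (SD over all raw band
#'   pixels).
#' @param normalize divide intensities by the cytoplasm mean first, making
#'   the statistic gain-invariant for cross-cell comparison. Default
#'   `FALSE` (raw intensity units).
#' @return list with `corticalSd`, the `profile` data.frame
#'   (bin, angle_rad, mean_intensity, n_pixels) and `flags`.
#' @export
corticalAsymmetry <- function(img, part, cell, nBins = 360L,
                              mode = c("bin_means", "pixels"),
                              normalize = FALSE) {
  mode <- match.arg(mode)
  stopIfNot(nBins >= 8L, "nBins must be >= 8")
  stopIfNot(any(part@bandMask), "empty cortical band")
  prof <- binBandPixels(img, part, cell, as.integer(nBins))
  flags <- character()
  if (mean(is.na(prof$mean_intensity)) > 0.25) flags <- "concave"
  scale <- 1
  if (normalize) {
    stopIfNot(any(part@cytoplasmMask), "no cytoplasm to normalize by")
    scale <- mean(img@pixels[part@cytoplasmMask])
  }
  sdv <- if (mode == "bin_means")
    stats::sd(prof$mean_intensity[!is.na(prof$mean_intensity)] / scale)
  else stats::sd(img@pixels[part@bandMask] / scale)
  prof$mean_intensity <- prof$mean_intensity / scale
  list(corticalSd = sdv, profile = prof, flags = flags)
}

#' Peripheral intensity profile
#'
#' The binned intensity profile around the entire cell periphery (the same
#' binning as [corticalAsymmetry]), optionally normalized by the cytoplasm
#' mean.
#'
#' @inheritParams corticalAsymmetry
#' @param normalize divide by the cytoplasm mean (mode recorded in the
#'   `normalization` attribute).
#' @return data.frame (bin, angle_rad, mean_intensity, n_pixels) with
#'   attributes `normalization` and `flags`.
#' @export
peripheralProfile <- function(img, part, cell, nBins = 360L,
                              normalize = FALSE) {
  res <- corticalAsymmetry(img, part, cell, nBins = nBins,
                           normalize = normalize)
  prof <- res$profile
  attr(prof, "normalization") <- if (normalize) "cytoplasm_mean" else "none"
  attr(prof, "flags") <- res$flags
  prof
}

#' Compute per-cell metrics for a segmented cell
#'
#' Convenience wrapper producing the three headline per-cell statistics:
#' cortex:cytoplasm ratio, cortical SD and filopodium count.
#'
#' @param img a [Micrograph-class].
#' @param cell a [CellRecord-class].
#' @param bandWidthUm cortical band width (um), default 0.8.
#' @param nBins angular bins for the asymmetry statistic.
#' @param tipConfig settings from [tipSearchConfig].
#' @param allCells all cells in the field (for background statistics of the
#'   tip search); defaults to just `cell`.
#' @return one-row data.frame: cell_id, cortex_cyto_ratio, cortical_sd,
#'   filopodia_count, qc_flags.
#' @export
cellMetrics <- function(img, cell, bandWidthUm = 0.8, nBins = 360L,
                        tipConfig = tipSearchConfig(),
                        allCells = list(cell)) {
  part <- partitionCortex(cell, bandWidthUm)
  flags <- unique(c(cell@flags, part@flags))
  if ("unmeasurable" %in% flags) {
    ratio <- NA_real_
    sdv <- NA_real_
    ntips <- NA_integer_
  } else {
    ratio <- cortexCytoRatio(img, part)
    asym <- corticalAsymmetry(img, part, cell, nBins = nBins)
    sdv <- asym$corticalSd
    flags <- unique(c(flags, asym$flags))
    tips <- radialTipSearch(img, cell, tipConfig, allCells = allCells)
    ntips <- nrow(tips)
  }
  data.frame(cell_id = cell@cellId, cortex_cyto_ratio = ratio,
             cortical_sd = sdv, filopodia_count = ntips,
             qc_flags = paste(flags, collapse = ";"))
}
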