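#' Segmentation configuration
#'
#' @param method thresholding method, `"otsu"` (parameter-free,
#'   intensity-scale invariant) or `"fixed"`.
#' @param value fixed threshold (same units as the image) when
#'   `method = "fixed"`.
#' @param bodyOpenUm radius of the morphological opening that removes thin
#'   protrusions (filopodia) from the body mask; structures thinner than
#'   about twice this are erased. Default 0.5 um.
#' @param nucleusFraction interior pixels darker than this fraction of the
#'   in-cell median are nucleus candidates. Default 0.5.
#' @param nucleusMinAreaUm2 minimum nucleus area (um^2). Default 2.
#' @param minCellAreaUm2 minimum cell area (um^2). Default 20.
#' @param expressionMin minimum mean in-cell intensity; `NULL` (default)
#'   uses background mean + 3 x background SD, operationalizing the
#'   exclusion of cells that do not express the fluorescent transgene.
#' @param excludeBorder drop cells touching the image border (their
#'   band/cytoplasm partition would be truncated). Default `TRUE`.
#' @return a named list of validated settings.
#' @export
segmentationConfig <- function(method = c("otsu", "fixed"), value = NULL,
                               bodyOpenUm = 0.5, nucleusFraction = 0.5,
                               nucleusMinAreaUm2 = 2, minCellAreaUm2 = 20,
                               expressionMin = NULL, excludeBorder = TRUE) {
  method <- match.arg(method)
  if (method == "fixed")
    stopIfNot(is.numeric(value) && length(value) == 1L && value > 0,
              "fixed thresholding needs a positive 'value'")
  stopIfNot(bodyOpenUm >= 0, "bodyOpenUm must be >= 0")
  stopIfNot(nucleusFraction > 0 && nucleusFraction < 1,
            "nucleusFraction must be in (0, 1)")
  list(method = method, value = value, bodyOpenUm = bodyOpenUm,
       nucleusFraction = nucleusFraction,
       nucleusMinAreaUm2 = nucleusMinAreaUm2,
       minCellAreaUm2 = minCellAreaUm2, expressionMin = expressionMin,
       excludeBorder = excludeBorder)
}

# Ordered boundary contour of a filled mask, closed (first vertex repeated).
maskContour <- function(filled) {
  oc <- EBImage::ocontour(EBImage::Image(filled * 1))
  if (length(oc) == 0L) return(matrix(numeric(0), 0L, 2L))
  ct <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # ocontour returns 0-based (x, y) in EBImage's (dim1, dim2) order, which
  # for a plain matrix is (row, col)
  ct <- ct + 1
  rbind(ct, ct[1L, , drop = FALSE])
}

#' Segment cells in a micrograph
#'
#' Thresholds the image (Otsu by default, on the intensity range rescaled to
#' [0, 1], so segmentation is invariant to global intensity scaling),
#' removes thin protrusions by a morphological opening, and labels connected
#' components as cells. The nucleus is detected photometrically as the union
#' of interior holes of the thresholded mask and interior regions darker
#' than `nucleusFraction` times the in-cell median, keeping regions of at
#' least `nucleusMinAreaUm2`. Cells touching the border are flagged
#' `"border"` and excluded by default; cells with mean intensity below the
#' expression floor are flagged `"low_expression"` and excluded.
#'
#' @param img a [Micrograph-class].
#' @param config settings from [segmentationConfig].
#' @param keepFlagged return flagged (border / low-expression) cells too,
#'   with their flags set, instead of dropping them.
#' @return list of [CellRecord-class] objects (possibly empty).
#' @export
segmentCells <- function(img, config = segmentationConfig(),
                         keepFlagged = FALSE) {
  stopIfNot(is(img, "Micrograph"), "img must be a Micrograph")
  px <- img@pixels
  stopIfNot(all(is.finite(px)), "image contains non-finite pixels")
  ps <- img@pixelSizeUm
  if (max(px) == 0) return(list())

  xn <- px / max(px)
  thr <- if (config$method == "otsu")
    EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  else config$value / max(px)
  mask <- xn > thr

  if (config$bodyOpenUm > 0) {
    # opening erases structures thinner than ~2 x bodyOpenUm (filopodia);
    # dilating back and intersecting with the original mask restores the
    # jagged boundary pixels the opening shaved off the body itself, so the
    # band partition is not biased inward
    rpx <- config$bodyOpenUm / ps
    size <- max(3L, 2L * as.integer(round(rpx)) + 1L)
    brush <- EBImage::makeBrush(size, "disc")
    opened <- EBImage::opening(EBImage::Image(mask * 1), brush)
    mask <- (asPlainMatrix(EBImage::dilate(opened, brush)) > 0) & mask
  }

  labels <- asPlainMatrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(labels)
  if (nlab == 0L) return(list())

  # background statistics for the expression floor: pixels well clear of
  # any segmented object
  allFilled <- asPlainMatrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  bgd <- distanceToBackground(!allFilled)
  bgPix <- px[!allFilled & bgd > 3 / ps]
  if (length(bgPix) < 50L) bgPix <- px[!allFilled]
  exprMin <- config$expressionMin
  if (is.null(exprMin)) exprMin <- mean(bgPix) + 3 * stats::sd(bgPix)

  nr <- nrow(px)
  nc <- ncol(px)
  cells <- list()
  cid <- 0L
  for (l in seq_len(nlab)) {
    comp <- labels == l
    filled <- asPlainMatrix(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
    areaUm2 <- sum(filled) * ps^2
    if (areaUm2 < config$minCellAreaUm2) next

    flags <- character()
    idx <- which(filled, arr.ind = TRUE)
    if (config$excludeBorder &&
        (any(idx[, 1L] %in% c(1L, nr)) || any(idx[, 2L] %in% c(1L, nc))))
      flags <- c(flags, "border")

    medIn <- stats::median(px[comp])
    holes <- filled & !comp
    dark <- filled & (px < config$nucleusFraction * medIn)
    nucCand <- holes | dark
    nucleus <- matrix(FALSE, nr, nc)
    if (any(nucCand)) {
      nucLab <- asPlainMatrix(EBImage::bwlabel(EBImage::Image(nucCand * 1)))
      for (nl in seq_len(max(nucLab))) {
        reg <- nucLab == nl
        if (sum(reg) * ps^2 >= config$nucleusMinAreaUm2)
          nucleus <- nucleus | reg
      }
    }
    body <- filled & !nucleus

    exprMean <- mean(px[body])
    if (exprMean < exprMin) flags <- c(flags, "low_expression")
    if (length(flags) && !keepFlagged) next

    centroid <- c(mean(idx[, 1L]), mean(idx[, 2L]))
    cid <- cid + 1L
    cells[[cid]] <- new("CellRecord", cellId = cid, bodyMask = body,
                        nucleusMask = nucleus, filledMask = filled,
                        centroid = centroid, boundary = maskContour(filled),
                        areaUm2 = areaUm2, expressionMean = exprMean,
                        pixelSizeUm = ps, flags = flags)
  }
  cells
}

#' Partition a cell into cortical band, cytoplasm and nucleus
#'
#' The cortical band is the set of filled-body pixels whose exact Euclidean
#' distance to the cell boundary is at most `bandWidthUm`. Distances are
#' computed on the filled body (so the nucleus hole does not create an
#' internal boundary) as the exact Euclidean distance transform to the
#' nearest background pixel center, corrected by the mean quarter-pixel
#' offset between background pixel centers and the continuous boundary; the
#' sub-pixel threshold is applied without rounding, so the band area of an
#' ideal disk matches the analytic annulus to about 1%. Cytoplasm is the filled body minus band
#' minus nucleus. The three masks partition the filled body exactly.
#'
#' @param cell a [CellRecord-class].
#' @param bandWidthUm band width in micrometres (default 0.8).
#' @param pixelSizeUm pixel size; defaults to the cell's.
#' @return a [CorticalPartition-class]; when the band consumes the whole
#'   cell (cell thinner than twice the band) the partition is flagged
#'   `"unmeasurable"` rather than returning an empty cytoplasm silently.
#' @examples
#' sc <- makeCellScene(SceneParams(gaussianSd = 0, poissonScale = 0))
#' cell <- segmentCells(maxProject(sc$stack))[[1]]
#' part <- partitionCortex(cell)
#' part
#' @export
partitionCortex <- function(cell, bandWidthUm = 0.8,
                            pixelSizeUm = cell@pixelSizeUm) {
  stopIfNot(is(cell, "CellRecord"), "cell must be a CellRecord")
  stopIfNot(bandWidthUm > 0, "bandWidthUm must be > 0")
  filled <- cell@filledMask
  d <- distanceToBackground(filled)
  band <- filled & (d <= bandDistanceThreshold(bandWidthUm, pixelSizeUm)) &
    !cell@nucleusMask
  cyto <- filled & !band & !cell@nucleusMask
  flags <- character()
  if (!any(cyto)) flags <- "unmeasurable"
  new("CorticalPartition", bandMask = band, cytoplasmMask = cyto,
      nucleusMask = cell@nucleusMask, bandWidthUm = bandWidthUm,
      flags = flags)
}

#' Export cell masks as run-length encodings
#'
#' @param cells list of [CellRecord-class].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
writeMasks <- function(cells, path) {
  enc <- lapply(cells, function(cc) {
    list(cell_id = cc@cellId, body = maskToRLE(cc@bodyMask),
         nucleus = maskToRLE(cc@nucleusMask),
         centroid = cc@centroid, area_um2 = cc@areaUm2,
         flags = cc@flags)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
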