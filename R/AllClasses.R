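#' @import methods
NULL

#' Single-channel 2-D micrograph
#'
#' A non-negative intensity grid with its physical pixel size. All
#' quantification in the package operates on `Micrograph` objects, typically
#' maximum-intensity projections of a [ZStack].
#'
#' Image coordinates are row-major with the origin at the top-left pixel
#' center; y (row index) increases downward. All micron/pixel conversions go
#' through `pixelSizeUm` without implicit rounding.
#'
#' @slot pixels numeric matrix of intensities (arbitrary units), finite and
#'   non-negative.
#' @slot pixelSizeUm physical size of one pixel in micrometres.
#' @slot channel channel label.
#' @slot provenance free-text provenance (source file, projection flag).
#' @exportClass Micrograph
setClass("Micrograph",
  representation(pixels = "matrix", pixelSizeUm = "numeric",
                 channel = "character", provenance = "character"),
  prototype(pixelSizeUm = 0.212, channel = "ch1", provenance = "unknown"))

setValidity("Micrograph", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  else {
    if (any(!is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
    else if (any(object@pixels < 0)) msg <- c(msg, "pixels must be >= 0")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Multi-slice image stack
#'
#' An ordered list of equally shaped intensity grids (z-sections) from one
#' channel. Downstream analysis runs on the maximum-intensity projection
#' ([maxProject]).
#'
#' @slot slices list of numeric matrices, all the same shape.
#' @slot pixelSizeUm physical pixel size in micrometres.
#' @slot channel channel label.
#' @slot zStepUm z spacing in micrometres (`NA` when unknown).
#' @exportClass ZStack
setClass("ZStack",
  representation(slices = "list", pixelSizeUm = "numeric",
                 channel = "character", zStepUm = "numeric"),
  prototype(pixelSizeUm = 0.212, channel = "ch1", zStepUm = NA_real_))

setValidity("ZStack", function(object) {
  msg <- character()
  if (length(object@slices) < 1L) msg <- c(msg, "need at least one slice")
  else {
    d <- dim(object@slices[[1L]])
    same <- vapply(object@slices,
                   function(s) is.matrix(s) && identical(dim(s), d),
                   logical(1))
    if (!all(same)) msg <- c(msg, "all slices must be matrices of one shape")
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Parameters of one synthetic cell scene
#'
#' Describes the geometry, photometry and noise of a synthetic fluorescence
#' scene with known ground truth. Defaults emulate vegetative amoeboid cells
#' imaged on a spinning-disk confocal: 0.212 um pixels, a cortical band of
#' 0.8 um, cytoplasmic level 100 a.u. over a background of 10 a.u., and
#' shot-plus-read noise over 5 z-sections.
#'
#' The cell outline is a circle of radius `cellRadiusUm` perturbed by a
#' low-order (orders 2-5) cosine series with total amplitude
#' `boundaryRoughness`, so the outline is smooth but non-circular and the
#' analytic annulus remains computable at roughness 0. The cortical band has
#' mean intensity `enrichment * cytoplasmLevel`, modulated angularly by
#' `1 + polarityAmplitude * cos(angle - polarityAngle)`. Filopodia are thin
#' rays anchored on the boundary with a Gaussian tip punctum of amplitude
#' `tipGain` times the shaft intensity.
#'
#' @slot imageShape integer (rows, cols) of the rendered frame.
#' @slot pixelSizeUm physical pixel size (um), default 0.212.
#' @slot cellRadiusUm mean cell radius (um).
#' @slot boundaryRoughness total amplitude of the radial perturbation
#'   (dimensionless; 0 gives a perfect disk).
#' @slot nucleusRadiusUm,nucleusOffsetUm nucleus radius and displacement of
#'   its center from the cell centroid (um); the nucleus must stay strictly
#'   inside the body.
#' @slot cytoplasmLevel,backgroundLevel intensities (a.u.).
#' @slot enrichment cortical enrichment factor E >= 0 (band mean =
#'   E x cytoplasm mean).
#' @slot polarityAmplitude polarity amplitude A, |A| < 1.
#' @slot polarityAngle polarity angle theta0 (radians).
#' @slot bandWidthUm cortical band width (um), default 0.8.
#' @slot nFilopodia number of filopodia k.
#' @slot filopodiumLengthUm,filopodiumWidthUm,tipGain filopodium geometry and
#'   tip amplification.
#' @slot poissonScale,gaussianSd noise model: rendered variance is
#'   `poissonScale * mean + gaussianSd^2`.
#' @slot nSlices number of z-sections (each an independent noise draw of the
#'   shared ideal image).
#' @slot channelCorrelation pixel-wise correlation rho of a second channel,
#'   in [-1, 1].
#' @slot seed integer seed; fully determines the rendered output.
#' @exportClass SceneParams
setClass("SceneParams",
  representation(imageShape = "integer", pixelSizeUm = "numeric",
                 cellRadiusUm = "numeric", boundaryRoughness = "numeric",
                 nucleusRadiusUm = "numeric", nucleusOffsetUm = "numeric",
                 cytoplasmLevel = "numeric", backgroundLevel = "numeric",
                 enrichment = "numeric", polarityAmplitude = "numeric",
                 polarityAngle = "numeric", bandWidthUm = "numeric",
                 nFilopodia = "integer", filopodiumLengthUm = "numeric",
                 filopodiumWidthUm = "numeric", tipGain = "numeric",
                 poissonScale = "numeric", gaussianSd = "numeric",
                 nSlices = "integer", channelCorrelation = "numeric",
                 seed = "integer"))

setValidity("SceneParams", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two integers >= 8")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@cellRadiusUm <= 0) msg <- c(msg, "cellRadiusUm must be > 0")
  if (object@boundaryRoughness < 0 || object@boundaryRoughness >= 1)
    msg <- c(msg, "boundaryRoughness must be in [0, 1)")
  if (object@enrichment < 0) msg <- c(msg, "enrichment must be >= 0")
  if (abs(object@polarityAmplitude) >= 1)
    msg <- c(msg, "polarityAmplitude must satisfy |A| < 1")
  if (object@bandWidthUm <= 0) msg <- c(msg, "bandWidthUm must be > 0")
  if (object@nucleusRadiusUm < 0) msg <- c(msg, "nucleusRadiusUm must be >= 0")
  if (object@nucleusRadiusUm > 0 &&
      object@nucleusOffsetUm + object@nucleusRadiusUm >=
        object@cellRadiusUm * (1 - object@boundaryRoughness))
    msg <- c(msg, "nucleus must lie strictly inside the cell body")
  if (object@nFilopodia < 0L) msg <- c(msg, "nFilopodia must be >= 0")
  if (object@nFilopodia > 0L && object@filopodiumLengthUm <= 0)
    msg <- c(msg, "filopodiumLengthUm must be > 0")
  if (object@nFilopodia > 0L && object@filopodiumWidthUm <= 0)
    msg <- c(msg, "filopodiumWidthUm must be > 0")
  if (object@poissonScale < 0 || object@gaussianSd < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (abs(object@channelCorrelation) > 1)
    msg <- c(msg, "channelCorrelation must be in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic scene
#'
#' Per-cell masks and generating parameters of a synthetic scene, used as the
#' oracle in parameter-recovery tests. Each element of `cells` is a list with
#' the cell's `cellId`, `bodyMask` (interior minus nucleus), `nucleusMask`,
#' `bandMask` (at the stated band width), `filledMask`, `centroid`
#' (row, col), generating `enrichment`, `polarityAmplitude`,
#' `polarityAngle`, and filopodium `tipRow`/`tipCol`/`baseAngle` vectors.
#'
#' @slot cells list of per-cell truth records.
#' @slot rho true pixel-wise correlation of the second channel (`NA` for
#'   single-channel scenes).
#' @slot params the generating [SceneParams] (or list of them for fields).
#' @slot seed master seed of the render.
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(cells = "list", rho = "numeric", params = "ANY",
                 seed = "integer"),
  prototype(rho = NA_real_))

#' One segmented cell
#'
#' Masks and geometry of a single segmented cell. `bodyMask` is the cell
#' interior including the cortical band but excluding the nucleus hole;
#' `filledMask` is the body with the nucleus filled in (the domain on which
#' boundary distances are measured).
#'
#' @slot cellId integer id within the field.
#' @slot bodyMask,nucleusMask,filledMask logical matrices.
#' @slot centroid (row, col) of the filled body, in pixels.
#' @slot boundary ordered closed contour, one (row, col) per vertex.
#' @slot areaUm2 filled-body area in square micrometres.
#' @slot expressionMean mean in-cell intensity (expression proxy).
#' @slot pixelSizeUm pixel size the masks were computed at.
#' @slot flags character vector of QC flags ("border", "low_expression",
#'   "unmeasurable", ...).
#' @exportClass CellRecord
setClass("CellRecord",
  representation(cellId = "integer", bodyMask = "matrix",
                 nucleusMask = "matrix", filledMask = "matrix",
                 centroid = "numeric", boundary = "matrix",
                 areaUm2 = "numeric", expressionMean = "numeric",
                 pixelSizeUm = "numeric", flags = "character"),
  prototype(flags = character()))

setValidity("CellRecord", function(object) {
  msg <- character()
  if (!identical(dim(object@bodyMask), dim(object@nucleusMask)) ||
      !identical(dim(object@bodyMask), dim(object@filledMask)))
    msg <- c(msg, "masks must share one shape")
  if (any(object@nucleusMask & !object@filledMask))
    msg <- c(msg, "nucleus must lie inside the filled body")
  if (length(object@centroid) != 2L) msg <- c(msg, "centroid must be (row, col)")
  if (length(msg)) msg else TRUE
})

#' Cortical band / cytoplasm / nucleus partition
#'
#' Exhaustive, pairwise-disjoint partition of a cell's filled body into the
#' cortical band (pixels within `bandWidthUm` of the outside), the nucleus,
#' and the remaining cytoplasm. All intensity ratios are defined on this
#' partition.
#'
#' @slot bandMask,cytoplasmMask,nucleusMask logical matrices.
#' @slot bandWidthUm band width in micrometres.
#' @slot flags QC flags ("unmeasurable" when the band consumes the cell).
#' @exportClass CorticalPartition
setClass("CorticalPartition",
  representation(bandMask = "matrix", cytoplasmMask = "matrix",
                 nucleusMask = "matrix", bandWidthUm = "numeric",
                 flags = "character"),
  prototype(flags = character()))

setValidity("CorticalPartition", function(object) {
  msg <- character()
  if (any((object@bandMask & object@cytoplasmMask) |
          (object@bandMask & object@nucleusMask) |
          (object@cytoplasmMask & object@nucleusMask)))
    msg <- c(msg, "band, cytoplasm and nucleus must be pairwise disjoint")
  if (object@bandWidthUm <= 0) msg <- c(msg, "bandWidthUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Pixel-wise two-channel cytofluorogram
#'
#' Paired in-mask pixel intensities of two channels with their Pearson
#' correlation coefficient r, the standard read-out of pixel-wise
#' colocalization.
#'
#' @slot a,b paired pixel intensities.
#' @slot r Pearson correlation.
#' @slot n number of pixel pairs.
#' @slot provenance mask provenance ("field" or "cell").
#' @slot flags QC flags ("small_mask" below 100 pixels).
#' @exportClass Cytofluorogram
setClass("Cytofluorogram",
  representation(a = "numeric", b = "numeric", r = "numeric", n = "integer",
                 provenance = "character", flags = "character"),
  prototype(provenance = "field", flags = character()))
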