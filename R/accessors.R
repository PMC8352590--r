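#' Construct a Micrograph
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelSizeUm pixel size in micrometres.
#' @param channel channel label.
#' @param provenance provenance string.
#' @return a [Micrograph-class] object.
#' @examples
#' m <- Micrograph(matrix(runif(100), 10), pixelSizeUm = 0.212)
#' pixelSizeUm(m)
#' @export
Micrograph <- function(pixels, pixelSizeUm = 0.212, channel = "ch1",
                       provenance = "in_memory") {
  new("Micrograph", pixels = pixels, pixelSizeUm = pixelSizeUm,
      channel = channel, provenance = provenance)
}

#' Construct a ZStack
#'
#' @param slices list of numeric matrices (z-sections), all the same shape.
#' @param pixelSizeUm pixel size in micrometres.
#' @param channel channel label.
#' @param zStepUm z spacing in micrometres.
#' @return a [ZStack-class] object.
#' @export
ZStack <- function(slices, pixelSizeUm = 0.212, channel = "ch1",
                   zStepUm = NA_real_) {
  new("ZStack", slices = slices, pixelSizeUm = pixelSizeUm,
      channel = channel, zStepUm = zStepUm)
}

#' Accessors for image and cell objects
#'
#' `pixels` returns the intensity matrix; `pixelSizeUm` the physical pixel
#' size; `nSlices` the number of z-sections; `bodyMask`, `nucleusMask`,
#' `bandMask` and `cytoplasmMask` the respective logical masks.
#'
#' @param x an object of the appropriate class.
#' @return matrix, numeric or integer as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Micrograph", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "Micrograph", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "ZStack", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setMethod("nSlices", "ZStack", function(x) length(x@slices))

#' @rdname accessors
#' @export
setGeneric("bodyMask", function(x) standardGeneric("bodyMask"))
#' @rdname accessors
#' @export
setMethod("bodyMask", "CellRecord", function(x) x@bodyMask)

#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))
#' @rdname accessors
#' @export
setMethod("nucleusMask", "CellRecord", function(x) x@nucleusMask)
#' @rdname accessors
#' @export
setMethod("nucleusMask", "CorticalPartition", function(x) x@nucleusMask)

#' @rdname accessors
#' @export
setGeneric("bandMask", function(x) standardGeneric("bandMask"))
#' @rdname accessors
#' @export
setMethod("bandMask", "CorticalPartition", function(x) x@bandMask)

#' @rdname accessors
#' @export
setGeneric("cytoplasmMask", function(x) standardGeneric("cytoplasmMask"))
#' @rdname accessors
#' @export
setMethod("cytoplasmMask", "CorticalPartition", function(x) x@cytoplasmMask)

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setMethod("qcFlags", "CellRecord", function(x) x@flags)
#' @rdname accessors
#' @export
setMethod("qcFlags", "CorticalPartition", function(x) x@flags)

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph %dx%d px (%.3f um/px), channel '%s' [%s]\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSizeUm,
              object@channel, object@provenance))
})

setMethod("show", "ZStack", function(object) {
  d <- dim(object@slices[[1L]])
  cat(sprintf("ZStack %d slices of %dx%d px (%.3f um/px), channel '%s'\n",
              length(object@slices), d[[1L]], d[[2L]], object@pixelSizeUm,
              object@channel))
})

setMethod("show", "SceneTruth", function(object) {
  k <- vapply(object@cells, function(cc) length(cc$tipRow), integer(1))
  cat(sprintf("SceneTruth: %d cell(s), %d filopodium tip(s), seed %d\n",
              length(object@cells), sum(k), object@seed))
})

setMethod("show", "CellRecord", function(object) {
  cat(sprintf(
    "CellRecord #%d: area %.1f um2, centroid (%.1f, %.1f), flags: %s\n",
    object@cellId, object@areaUm2, object@centroid[[1L]],
    object@centroid[[2L]],
    if (length(object@flags)) paste(object@flags, collapse = ",") else "none"))
})

setMethod("show", "CorticalPartition", function(object) {
  cat(sprintf(
    "CorticalPartition: band %d px, cytoplasm %d px, nucleus %d px (band %.2f um)\n",
    sum(object@bandMask), sum(object@cytoplasmMask), sum(object@nucleusMask),
    object@bandWidthUm))
})

setMethod("show", "Cytofluorogram", function(object) {
  cat(sprintf("Cytofluorogram: r = %.3f over %d pixels (%s)\n",
              object@r, object@n, object@provenance))
})
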