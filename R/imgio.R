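#' Write an image stack to TIFF with a JSON metadata sidecar
#'
#' Pages are written in the order given by `stacks` (channels) and slices
#' within each channel ("cz" interleaving: all z of channel 1, then channel
#' 2, ...). TIFF samples are stored as 32-bit floats scaled into [0, 1] by a
#' per-file scale factor recorded in the sidecar, so arbitrary non-negative
#' intensities round-trip; with `bits16 = TRUE`, data are quantized to
#' 16-bit integers instead (lossless for integer data up to 65535). The
#' sidecar (`<path>.json`) records pixel size, z step, channel labels,
#' slice counts and the scale.
#'
#' @param stacks a [ZStack-class] or list of them (one per channel).
#' @param path output TIFF path.
#' @param bits16 store quantized 16-bit samples instead of floats.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stacks, path, bits16 = FALSE) {
  if (is(stacks, "ZStack")) stacks <- list(stacks)
  stopIfNot(all(vapply(stacks, is, logical(1), "ZStack")),
            "stacks must be ZStack objects")
  pages <- unlist(lapply(stacks, function(s) s@slices), recursive = FALSE)
  mx <- max(1e-12, max(vapply(pages, max, numeric(1))))
  scale <- if (bits16) 65535 else mx
  pages <- lapply(pages, function(p) pmin(p / scale, 1))
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (bits16) 16L else 32L,
                  reduce = FALSE)
  meta <- list(pixel_size_um = stacks[[1L]]@pixelSizeUm,
               z_step_um = stacks[[1L]]@zStepUm,
               channels = vapply(stacks, function(s) s@channel, character(1)),
               n_slices = vapply(stacks, nSlices, integer(1)),
               axis_order = "cz", scale = scale,
               sample_format = if (bits16) "uint16" else "float32")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a TIFF stack (one ZStack per channel)
#'
#' Reads a (multi-page) TIFF. Page-to-axis assignment and the pixel size are
#' resolved in this order of precedence: the JSON sidecar written by
#' [writeStack], then the `axisSpec`/`pixelSizeUm` arguments, then an error.
#' With `strict = FALSE` a missing pixel size falls back to 0.212 um (a
#' common EMCCD/63x configuration) with a prominent warning; every
#' downstream metric is calibrated in micrometres, so silent defaults are
#' refused in strict mode.
#'
#' @param path TIFF file path.
#' @param axisSpec list with `n_channels` and optionally `channels`
#'   (labels) and `axis_order` ("cz": channel-major page order). Ignored
#'   when a sidecar is present.
#' @param pixelSizeUm pixel-size override (um) used when no sidecar is
#'   present.
#' @param strict fail on a missing pixel size (default) instead of assuming
#'   0.212 um.
#' @return list of [ZStack-class] objects, one per channel.
#' @export
readStack <- function(path, axisSpec = list(), pixelSizeUm = NULL,
                      strict = TRUE) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    psz <- meta$pixel_size_um
    channels <- meta$channels
    nsl <- meta$n_slices
    scale <- meta$scale
    zstep <- if (is.null(meta$z_step_um) || !is.numeric(meta$z_step_um))
      NA_real_ else meta$z_step_um
    if (identical(meta$sample_format, "uint16")) {
      # readTIFF returns 16-bit data divided by 65535; undo exactly
      pages <- lapply(pages, function(p) round(p * 65535))
      scale <- scale / 65535
    }
  } else {
    psz <- pixelSizeUm
    if (is.null(psz)) {
      if (strict)
        stop("pixel size not in metadata; pass pixelSizeUm explicitly",
             call. = FALSE)
      warning("pixel size unknown; assuming 0.212 um/px", call. = FALSE)
      psz <- 0.212
    }
    nch <- axisSpec$n_channels
    if (is.null(nch)) nch <- 1L
    stopIfNot(length(pages) %% nch == 0,
              sprintf("%d pages do not divide into %d channels: ambiguous axes",
                      length(pages), nch))
    channels <- axisSpec$channels
    if (is.null(channels)) channels <- paste0("ch", seq_len(nch))
    nsl <- rep(length(pages) %/% nch, nch)
    scale <- 1
    zstep <- NA_real_
  }
  stopIfNot(sum(nsl) == length(pages),
            "page count disagrees with metadata: ambiguous axes")
  out <- vector("list", length(channels))
  off <- 0L
  for (i in seq_along(channels)) {
    sl <- lapply(pages[off + seq_len(nsl[[i]])], function(p) p * scale)
    out[[i]] <- ZStack(sl, pixelSizeUm = psz, channel = channels[[i]],
                       zStepUm = zstep)
    off <- off + nsl[[i]]
  }
  out
}

#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum over all slices; the projection is what every intensity
#' metric in the package is measured on.
#'
#' @param stack a [ZStack-class].
#' @return a [Micrograph-class] whose provenance marks the projection.
#' @examples
#' z <- ZStack(list(matrix(1, 4, 4), matrix(2, 4, 4)))
#' max(pixels(maxProject(z)))
#' @export
maxProject <- function(stack) {
  stopIfNot(is(stack, "ZStack") && length(stack@slices) >= 1L,
            "need a ZStack with at least one slice")
  proj <- Reduce(pmax, stack@slices)
  Micrograph(proj, pixelSizeUm = stack@pixelSizeUm, channel = stack@channel,
             provenance = "max_projection")
}

perCellSchema <- c("field_id", "cell_id", "experiment_id",
                   "cortex_cyto_ratio", "cortical_sd", "filopodia_count",
                   "qc_flags")

#' Write per-cell results and a JSON run summary
#'
#' Writes the per-cell metric table as UTF-8 comma-separated CSV (header
#' mandatory, '.' decimal) plus a JSON summary with the row count, a config
#' hash and the package version.
#'
#' @param records data.frame with columns `field_id`, `cell_id`,
#'   `experiment_id`, `cortex_cyto_ratio`, `cortical_sd`,
#'   `filopodia_count`, `qc_flags`.
#' @param path output CSV path; the summary goes to `<path>.summary.json`.
#' @param config optional configuration object hashed into the summary.
#' @return `path`, invisibly.
#' @export
writeResults <- function(records, path, config = NULL) {
  stopIfNot(is.data.frame(records), "records must be a data.frame")
  missing <- setdiff(perCellSchema, names(records))
  if (length(missing))
    stop("records missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  records <- records[, perCellSchema, drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  summary <- list(n_cells = nrow(records),
                  config_hash = objectHash(config),
                  version = as.character(utils::packageVersion("CortexQuant")))
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
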