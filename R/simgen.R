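#' Create scene parameters for the synthetic micrograph generator
#'
#' Convenience constructor with defaults emulating vegetative amoeboid cells
#' imaged live on a spinning-disk confocal: 0.212 um pixels, 4-6 z-sections
#' (default 5), a cell of radius 8 um with a mildly non-circular outline, a
#' dark nucleus, a 0.8 um cortical band at the requested enrichment and
#' polarity, and a Poisson-plus-Gaussian camera noise model.
#'
#' @param imageShape integer (rows, cols), default `c(128, 128)`.
#' @param pixelSizeUm pixel size (um), default 0.212.
#' @param cellRadiusUm mean cell radius (um), default 8.
#' @param boundaryRoughness total amplitude of the order-2..5 cosine
#'   perturbation of the outline, default 0.04.
#' @param nucleusRadiusUm,nucleusOffsetUm nucleus geometry (um), defaults
#'   2 and 1.5.
#' @param cytoplasmLevel,backgroundLevel intensities (a.u.), defaults 100
#'   and 10.
#' @param enrichment cortical enrichment factor E (band mean = E x cytoplasm
#'   mean), default 1.2.
#' @param polarityAmplitude,polarityAngle angular modulation of the band,
#'   `1 + A cos(angle - theta0)`; defaults 0 and 0.
#' @param bandWidthUm cortical band width (um), default 0.8.
#' @param nFilopodia number of filopodia, default 0.
#' @param filopodiumLengthUm,filopodiumWidthUm,tipGain filopodium geometry
#'   (defaults 3 um, 0.25 um) and tip punctum amplification (default 3).
#' @param poissonScale,gaussianSd noise model (rendered variance is
#'   `poissonScale * mean + gaussianSd^2`); defaults 1 and 5.
#' @param nSlices z-sections sharing one ideal image, default 5.
#' @param channelCorrelation pixel-wise correlation of a second channel,
#'   default 0.
#' @param seed integer seed fully determining the render, default 1.
#' @return a validated [SceneParams-class] object.
#' @examples
#' p <- SceneParams(enrichment = 1.5, seed = 7)
#' sc <- makeCellScene(p)
#' sc$stack
#' @export
SceneParams <- function(imageShape = c(128L, 128L), pixelSizeUm = 0.212,
                        cellRadiusUm = 8, boundaryRoughness = 0.04,
                        nucleusRadiusUm = 2, nucleusOffsetUm = 1.5,
                        cytoplasmLevel = 100, backgroundLevel = 10,
                        enrichment = 1.2, polarityAmplitude = 0,
                        polarityAngle = 0, bandWidthUm = 0.8,
                        nFilopodia = 0L, filopodiumLengthUm = 3,
                        filopodiumWidthUm = 0.25, tipGain = 3,
                        poissonScale = 1, gaussianSd = 5, nSlices = 5L,
                        channelCorrelation = 0, seed = 1L) {
  new("SceneParams", imageShape = as.integer(imageShape),
      pixelSizeUm = pixelSizeUm, cellRadiusUm = cellRadiusUm,
      boundaryRoughness = boundaryRoughness,
      nucleusRadiusUm = nucleusRadiusUm, nucleusOffsetUm = nucleusOffsetUm,
      cytoplasmLevel = cytoplasmLevel, backgroundLevel = backgroundLevel,
      enrichment = enrichment, polarityAmplitude = polarityAmplitude,
      polarityAngle = polarityAngle, bandWidthUm = bandWidthUm,
      nFilopodia = as.integer(nFilopodia),
      filopodiumLengthUm = filopodiumLengthUm,
      filopodiumWidthUm = filopodiumWidthUm, tipGain = tipGain,
      poissonScale = poissonScale, gaussianSd = gaussianSd,
      nSlices = as.integer(nSlices),
      channelCorrelation = channelCorrelation, seed = as.integer(seed))
}

# Draw k angles in [0, 2pi) with pairwise circular separation >= minSepRad,
# by rejection. Consumes the current RNG stream.
drawSeparatedAngles <- function(k, minSepRad = 15 * pi / 180) {
  if (k == 0L) return(numeric(0))
  stopIfNot(k * minSepRad < 2 * pi,
            "cannot place this many filopodia at the minimum separation")
  for (try in seq_len(1000L)) {
    a <- sort(stats::runif(k, 0, 2 * pi))
    gaps <- if (k == 1L) 2 * pi else c(diff(a), 2 * pi - (a[k] - a[1L]))
    if (all(gaps >= minSepRad)) return(a)
  }
  stop("failed to draw separated filopodium angles", call. = FALSE)
}

# Render the noiseless ideal image of one cell plus its truth masks.
# Consumes the current RNG stream (boundary phases, nucleus direction,
# filopodium angles); apply withr::with_seed around it for determinism.
renderIdealScene <- function(params, center = NULL,
                             shape = params@imageShape) {
  ps <- params@pixelSizeUm
  nr <- shape[[1L]]
  nc <- shape[[2L]]
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- rowg - center[[1L]]
  dx <- colg - center[[2L]]
  phi <- atan2(dy, dx)
  rad <- sqrt(dx^2 + dy^2)

  # boundary radius R(phi): orders 2-5 cosine perturbation whose amplitudes
  # sum to boundaryRoughness, so max radial deviation is bounded by it
  if (params@boundaryRoughness > 0) {
    w <- abs(stats::rnorm(4L))
    w <- w / sum(w) * params@boundaryRoughness
    ph <- stats::runif(4L, 0, 2 * pi)
  } else {
    w <- rep(0, 4L)
    ph <- rep(0, 4L)
  }
  orders <- 2:5
  pert <- matrix(0, nr, nc)
  for (j in seq_along(orders))
    pert <- pert + w[[j]] * cos(orders[[j]] * phi + ph[[j]])
  Rphi <- params@cellRadiusUm * (1 + pert)
  filled <- rad <= Rphi / ps

  if (params@nucleusRadiusUm > 0) {
    na <- stats::runif(1L, 0, 2 * pi)
    nctr <- center + params@nucleusOffsetUm / ps * c(sin(na), cos(na))
    nucleus <- ((rowg - nctr[[1L]])^2 + (colg - nctr[[2L]])^2) <=
      (params@nucleusRadiusUm / ps)^2
    nucleus <- nucleus & filled
  } else {
    nucleus <- matrix(FALSE, nr, nc)
  }

  d <- distanceToBackground(filled)
  band <- filled & (d <= bandDistanceThreshold(params@bandWidthUm, ps)) &
    !nucleus
  cyto <- filled & !band & !nucleus

  ideal <- matrix(params@backgroundLevel, nr, nc)
  ideal[cyto] <- params@cytoplasmLevel
  ideal[band] <- params@cytoplasmLevel * params@enrichment *
    (1 + params@polarityAmplitude * cos(phi[band] - params@polarityAngle))
  ideal[nucleus] <- 0

  k <- params@nFilopodia
  tipRow <- tipCol <- baseAngle <- numeric(0)
  if (k > 0L) {
    angles <- drawSeparatedAngles(k)
    Lpx <- params@filopodiumLengthUm / ps
    wpx <- params@filopodiumWidthUm / ps
    shaftLevel <- params@cytoplasmLevel
    outside <- !filled
    for (a in angles) {
      Rb <- params@cellRadiusUm *
        (1 + sum(w * cos(orders * a + ph))) / ps
      dirv <- c(sin(a), cos(a)) # (drow, dcol)
      p0 <- center + Rb * dirv
      p1 <- center + (Rb + Lpx) * dirv
      # distance of every pixel to the shaft segment [p0, p1]
      vy <- p1[[1L]] - p0[[1L]]
      vx <- p1[[2L]] - p0[[2L]]
      len2 <- vy^2 + vx^2
      t <- pmin(pmax(((rowg - p0[[1L]]) * vy + (colg - p0[[2L]]) * vx) / len2,
                     0), 1)
      dseg <- sqrt((rowg - (p0[[1L]] + t * vy))^2 +
                   (colg - (p0[[2L]] + t * vx))^2)
      shaft <- (dseg <= max(wpx / 2, 0.5)) & outside
      ideal[shaft] <- pmax(ideal[shaft], shaftLevel)
      # bright terminal punctum: Gaussian of sigma = filopodium width
      g <- params@tipGain * shaftLevel *
        exp(-((rowg - p1[[1L]])^2 + (colg - p1[[2L]])^2) / (2 * wpx^2))
      ideal <- ideal + g * outside
      tipRow <- c(tipRow, p1[[1L]])
      tipCol <- c(tipCol, p1[[2L]])
      baseAngle <- c(baseAngle, a)
    }
  }

  list(ideal = ideal, filled = filled, nucleus = nucleus, band = band,
       cytoplasm = cyto, centroid = center, tipRow = tipRow, tipCol = tipCol,
       baseAngle = baseAngle)
}

# One Poisson + Gaussian camera-noise realization of an ideal image,
# clipped at zero.
applyNoise <- function(ideal, poissonScale, gaussianSd) {
  out <- as.vector(ideal)
  if (poissonScale > 0)
    out <- poissonScale * stats::rpois(length(out), out / poissonScale)
  if (gaussianSd > 0)
    out <- out + stats::rnorm(length(out), 0, gaussianSd)
  matrix(pmax(out, 0), nrow(ideal), ncol(ideal))
}

truthCellFromScene <- function(scene, cellId, params) {
  list(cellId = as.integer(cellId),
       bodyMask = scene$filled & !scene$nucleus,
       nucleusMask = scene$nucleus, bandMask = scene$band,
       filledMask = scene$filled, centroid = scene$centroid,
       enrichment = params@enrichment,
       polarityAmplitude = params@polarityAmplitude,
       polarityAngle = params@polarityAngle,
       tipRow = scene$tipRow, tipCol = scene$tipCol,
       baseAngle = scene$baseAngle)
}

#' Render a synthetic single-cell scene with ground truth
#'
#' Renders the noiseless ideal image of one cell (background, cytoplasm,
#' dark nucleus, angularly modulated cortical band, filopodia with bright
#' tip puncta), then draws `nSlices` independent noise realizations of it.
#' The same seed always produces bit-identical output.
#'
#' @param params a [SceneParams-class] object.
#' @return a list with elements `stack` (a [ZStack-class] of `nSlices`
#'   noisy sections), `ideal` (the noiseless matrix) and `truth` (a
#'   [SceneTruth-class]).
#' @examples
#' sc <- makeCellScene(SceneParams(enrichment = 1.5, seed = 3))
#' img <- maxProject(sc$stack)
#' @export
makeCellScene <- function(params) {
  validObject(params)
  withr::with_seed(params@seed, {
    scene <- renderIdealScene(params)
    slices <- lapply(seq_len(params@nSlices), function(i) {
      if (params@poissonScale == 0 && params@gaussianSd == 0) scene$ideal
      else applyNoise(scene$ideal, params@poissonScale, params@gaussianSd)
    })
    truth <- new("SceneTruth",
                 cells = list(truthCellFromScene(scene, 1L, params)),
                 rho = NA_real_, params = params, seed = params@seed)
    list(stack = ZStack(slices, pixelSizeUm = params@pixelSizeUm,
                        channel = "sim"),
         ideal = scene$ideal, truth = truth)
  })
}

#' Render a correlated two-channel synthetic scene
#'
#' Channel A is a noisy render of the scene. Inside the cell mask, channel-B
#' fluctuations are constructed as `rho * zA + sqrt(1 - rho^2) * e`, where
#' `zA` is the standardized in-mask channel-A fluctuation and `e` is an
#' independent standardized noise field orthogonalized against `zA`, then
#' rescaled to channel-A levels and shifted to stay non-negative. The
#' in-mask sample Pearson correlation therefore equals `rho` exactly
#' (affine shifts and positive rescaling leave Pearson r unchanged).
#' Outside the mask both channels carry independent background noise.
#'
#' @param params a [SceneParams-class] object.
#' @param rho target pixel-wise correlation in `[-1, 1]`; defaults to
#'   `params@channelCorrelation`.
#' @return list with `chA`, `chB` (both [Micrograph-class]) and `truth`
#'   (a [SceneTruth-class] whose `rho` slot records the target).
#' @export
makeTwoChannelScene <- function(params, rho = params@channelCorrelation) {
  validObject(params)
  stopIfNot(is.numeric(rho) && length(rho) == 1L && abs(rho) <= 1,
            "rho must be a single value in [-1, 1]")
  withr::with_seed(params@seed, {
    scene <- renderIdealScene(params)
    A <- applyNoise(scene$ideal, params@poissonScale, params@gaussianSd)
    mask <- scene$filled
    a <- A[mask]
    stopIfNot(stats::sd(a) > 0, "channel A is constant inside the mask")
    zA <- (a - mean(a)) / stats::sd(a)
    e <- stats::rnorm(length(a))
    e <- e - mean(e)
    e <- e - sum(e * zA) / sum(zA * zA) * zA # exact orthogonality
    e <- e / stats::sd(e)
    zB <- rho * zA + sqrt(1 - rho^2) * e
    b <- mean(a) + stats::sd(a) * zB
    b <- b - min(min(b), 0) # affine shift, preserves Pearson r
    B <- applyNoise(matrix(params@backgroundLevel, nrow(A), ncol(A)),
                    params@poissonScale, params@gaussianSd)
    B[mask] <- b
    truth <- new("SceneTruth",
                 cells = list(truthCellFromScene(scene, 1L, params)),
                 rho = rho, params = params, seed = params@seed)
    list(chA = Micrograph(A, params@pixelSizeUm, "chA", "simulated"),
         chB = Micrograph(B, params@pixelSizeUm, "chB", "simulated"),
         truth = truth)
  })
}

#' Render a multi-cell field with non-overlapping cells
#'
#' Places each cell at a uniformly drawn position (rejection sampling),
#' requiring non-overlapping cell bodies with at least `minGapUm` between
#' body outlines and no contact with the image border. Per-cell geometry is
#' driven by seeds derived from `seed`, so results are reproducible and
#' independent of placement retries.
#'
#' @param params list of [SceneParams-class], one per cell. All cells must
#'   share pixel size, background level and noise model (taken from the
#'   first element).
#' @param fieldShape integer (rows, cols) of the composite field.
#' @param seed master seed; defaults to the first cell's seed.
#' @param maxAttempts placement attempts per cell before an explicit error.
#' @param minGapUm minimum gap between cell outlines (um).
#' @return list with `stack` (a [ZStack-class]), `ideal` and `truth` (per
#'   cell masks and tips, cells labeled in order of placement).
#' @export
makeField <- function(params, fieldShape = c(256L, 256L),
                      seed = params[[1L]]@seed, maxAttempts = 200L,
                      minGapUm = 2) {
  stopIfNot(is.list(params) && length(params) >= 1L,
            "params must be a non-empty list of SceneParams")
  lapply(params, validObject)
  p1 <- params[[1L]]
  shared <- vapply(params, function(p) {
    p@pixelSizeUm == p1@pixelSizeUm &&
      p@backgroundLevel == p1@backgroundLevel &&
      p@poissonScale == p1@poissonScale && p@gaussianSd == p1@gaussianSd &&
      p@nSlices == p1@nSlices
  }, logical(1))
  stopIfNot(all(shared),
            "all cells must share pixel size, background and noise model")
  ps <- p1@pixelSizeUm
  nr <- as.integer(fieldShape[[1L]])
  nc <- as.integer(fieldShape[[2L]])

  withr::with_seed(seed, {
    cellSeeds <- sample.int(.Machine$integer.max - 1L, length(params) + 1L)
    noiseSeed <- cellSeeds[[length(params) + 1L]]
    occupied <- matrix(FALSE, nr, nc)
    fieldIdeal <- matrix(p1@backgroundLevel, nr, nc)
    centers <- matrix(NA_real_, length(params), 2L)
    rmax <- vapply(params, function(p)
      p@cellRadiusUm * (1 + p@boundaryRoughness) / ps, numeric(1))
    # keep the whole structure, filopodia and tip puncta included, in frame
    reach <- vapply(params, function(p)
      if (p@nFilopodia > 0L)
        (p@filopodiumLengthUm + 3 * p@filopodiumWidthUm) / ps else 0,
      numeric(1))
    truthCells <- vector("list", length(params))

    for (i in seq_along(params)) {
      p <- params[[i]]
      margin <- rmax[[i]] + reach[[i]] + 2
      stopIfNot(nr - 2 * margin > 1 && nc - 2 * margin > 1,
                "field too small for this cell radius")
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        ctr <- c(stats::runif(1L, 1 + margin, nr - margin),
                 stats::runif(1L, 1 + margin, nc - margin))
        if (i > 1L) {
          dd <- sqrt((centers[seq_len(i - 1L), 1L] - ctr[[1L]])^2 +
                     (centers[seq_len(i - 1L), 2L] - ctr[[2L]])^2)
          if (any(dd < rmax[[i]] + rmax[seq_len(i - 1L)] + minGapUm / ps))
            next
        }
        scene <- withr::with_seed(cellSeeds[[i]],
                                  renderIdealScene(p, ctr, c(nr, nc)))
        if (any(scene$filled & occupied)) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place cell %d after %d attempts", i,
                     maxAttempts), call. = FALSE)
      centers[i, ] <- ctr
      occupied <- occupied | scene$filled
      fieldIdeal <- fieldIdeal + (scene$ideal - p@backgroundLevel)
      truthCells[[i]] <- truthCellFromScene(scene, i, p)
    }

    fieldIdeal <- pmax(fieldIdeal, 0)
    slices <- withr::with_seed(noiseSeed, {
      lapply(seq_len(p1@nSlices), function(s) {
        if (p1@poissonScale == 0 && p1@gaussianSd == 0) fieldIdeal
        else applyNoise(fieldIdeal, p1@poissonScale, p1@gaussianSd)
      })
    })
    truth <- new("SceneTruth", cells = truthCells, rho = NA_real_,
                 params = params, seed = as.integer(seed))
    list(stack = ZStack(slices, pixelSizeUm = ps, channel = "sim"),
         ideal = fieldIdeal, truth = truth)
  })
}

#' Build a CellRecord or CorticalPartition from generator truth
#'
#' Converts the ground-truth masks of a synthetic scene into the containers
#' the quantification operations consume, bypassing segmentation. Used to
#' validate individual statistics against known inputs (e.g. a closed-form
#' cosine-modulated band) independently of the thresholding stage.
#'
#' @param truth a [SceneTruth-class].
#' @param i cell index within the truth.
#' @param img optional [Micrograph-class] used to fill `expressionMean`.
#' @return `truthCellRecord`: a [CellRecord-class];
#'   `truthPartition`: a [CorticalPartition-class].
#' @export
truthCellRecord <- function(truth, i = 1L, img = NULL) {
  tc <- truth@cells[[i]]
  ps <- if (is.list(truth@params)) truth@params[[i]]@pixelSizeUm
        else truth@params@pixelSizeUm
  expr <- if (is.null(img)) NA_real_ else mean(img@pixels[tc$bodyMask])
  new("CellRecord", cellId = tc$cellId, bodyMask = tc$bodyMask,
      nucleusMask = tc$nucleusMask, filledMask = tc$filledMask,
      centroid = tc$centroid, boundary = maskContour(tc$filledMask),
      areaUm2 = sum(tc$filledMask) * ps^2, expressionMean = expr,
      pixelSizeUm = ps, flags = character())
}

#' @rdname truthCellRecord
#' @param bandWidthUm band width; defaults to the generating parameter.
#' @export
truthPartition <- function(truth, i = 1L, bandWidthUm = NULL) {
  tc <- truth@cells[[i]]
  p <- if (is.list(truth@params)) truth@params[[i]] else truth@params
  if (is.null(bandWidthUm) || bandWidthUm == p@bandWidthUm) {
    band <- tc$bandMask
    bw <- p@bandWidthUm
  } else {
    d <- distanceToBackground(tc$filledMask)
    band <- tc$filledMask &
      (d <= bandDistanceThreshold(bandWidthUm, p@pixelSizeUm)) &
      !tc$nucleusMask
    bw <- bandWidthUm
  }
  cyto <- tc$filledMask & !band & !tc$nucleusMask
  new("CorticalPartition", bandMask = band, cytoplasmMask = cyto,
      nucleusMask = tc$nucleusMask, bandWidthUm = bw,
      flags = if (any(cyto)) character() else "unmeasurable")
}
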