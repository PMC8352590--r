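#' Tip-search configuration
#'
#' @param dthetaDeg angular step of the ray fan (degrees), default 1.
#' @param maxLengthUm maximum search distance beyond the cell boundary
#'   (um), default 15.
#' @param kSigma detection threshold in background SDs above the background
#'   mean, default 4.
#' @param mergeAngleDeg candidates on rays closer than this are considered
#'   the same tip, default 5.
#' @param mergeRadiusUm ... and only if their radial positions (distance
#'   from the ray origin) agree within this (um), default 1.
#' @param bgMarginUm background statistics are estimated from pixels at
#'   least this far outside every cell body, default 3.
#' @param stepPx radial sampling step along each ray (pixels), default 0.5.
#' @return named list of validated settings.
#' @export
tipSearchConfig <- function(dthetaDeg = 1, maxLengthUm = 15, kSigma = 4,
                            mergeAngleDeg = 5, mergeRadiusUm = 1,
                            bgMarginUm = 3, stepPx = 0.5) {
  stopIfNot(dthetaDeg > 0 && dthetaDeg <= 30, "dthetaDeg must be in (0, 30]")
  stopIfNot(maxLengthUm > 0, "maxLengthUm must be > 0")
  stopIfNot(kSigma >= 0, "kSigma must be >= 0")
  list(dthetaDeg = dthetaDeg, maxLengthUm = maxLengthUm, kSigma = kSigma,
       mergeAngleDeg = mergeAngleDeg, mergeRadiusUm = mergeRadiusUm,
       bgMarginUm = bgMarginUm, stepPx = stepPx)
}

emptyTipTable <- function() {
  data.frame(tip_row = numeric(0), tip_col = numeric(0),
             angle_rad = numeric(0), distance_um = numeric(0),
             peak_intensity = numeric(0), cell_id = integer(0))
}

# Background mean and SD measured at least marginUm outside every body.
backgroundStats <- function(px, cells, pixelSizeUm, marginUm) {
  union <- Reduce(`|`, lapply(cells, function(cc) cc@filledMask))
  d <- distanceToBackground(!union)
  sel <- !union & d > marginUm / pixelSizeUm
  if (sum(sel) < 50L) sel <- !union
  c(mean = mean(px[sel]), sd = stats::sd(px[sel]))
}

#' Detect filopodium tips by radial search
#'
#' Casts rays from the cell centroid at `dthetaDeg` steps. Along each ray
#' the intensity is sampled (bilinear) from the body boundary outward to
#' `maxLengthUm`, truncating where the ray enters another cell's body; the
#' outermost local maximum exceeding
#' `background mean + kSigma x background SD` that is *rooted* -- connected
#' to the cell by elevated intensity (at least half of the samples between
#' the boundary and the peak above background mean + 2 SD), as a
#' protrusion extending from the cell must be -- is that ray's candidate
#' tip. Candidates on rays within `mergeAngleDeg` of each other whose
#' radial positions differ by at most `mergeRadiusUm` are clustered, and
#' each cluster is reported once, at the position of its brightest
#' candidate, refined to sub-pixel accuracy by a quadratic fit around the
#' 1-D ray peak.
#'
#' When the centroid lies outside the body (pathological concavity) the ray
#' origin falls back to the pole of inaccessibility (the body pixel
#' farthest from the background).
#'
#' @param img a [Micrograph-class].
#' @param cell a [CellRecord-class] segmented on the same geometry.
#' @param config settings from [tipSearchConfig].
#' @param allCells all cells in the field, used for the background
#'   estimate; defaults to `list(cell)`.
#' @return data.frame with columns tip_row, tip_col, angle_rad,
#'   distance_um, peak_intensity, cell_id (one row per tip; zero rows when
#'   none found).
#' @export
radialTipSearch <- function(img, cell, config = tipSearchConfig(),
                            allCells = list(cell)) {
  stopIfNot(is(img, "Micrograph") && is(cell, "CellRecord"),
            "need a Micrograph and a CellRecord")
  if ("unmeasurable" %in% cell@flags) {
    warning("skipping unmeasurable cell", call. = FALSE)
    return(emptyTipTable())
  }
  px <- img@pixels
  ps <- img@pixelSizeUm
  nr <- nrow(px)
  nc <- ncol(px)
  filled <- cell@filledMask

  bg <- backgroundStats(px, allCells, ps, config$bgMarginUm)
  thr <- bg[["mean"]] + config$kSigma * bg[["sd"]]
  rootThr <- bg[["mean"]] + 2 * bg[["sd"]]
  otherBodies <- Reduce(`|`, lapply(
    Filter(function(cc) cc@cellId != cell@cellId, allCells),
    function(cc) cc@filledMask), matrix(FALSE, nr, nc))

  origin <- cell@centroid
  oi <- round(origin)
  if (oi[[1L]] < 1 || oi[[1L]] > nr || oi[[2L]] < 1 || oi[[2L]] > nc ||
      !filled[oi[[1L]], oi[[2L]]]) {
    d <- distanceToBackground(filled)
    w <- which(d == max(d), arr.ind = TRUE)[1L, ]
    origin <- as.numeric(w)
  }

  step <- config$stepPx
  Lpx <- config$maxLengthUm / ps
  thetas <- seq(0, 2 * pi - 1e-9, by = config$dthetaDeg * pi / 180)
  cand <- list()
  for (th in thetas) {
    drow <- sin(th)
    dcol <- cos(th)
    # longest admissible radius before leaving the frame
    tmax <- min(
      if (drow > 0) (nr - origin[[1L]]) / drow
      else if (drow < 0) (1 - origin[[1L]]) / drow else Inf,
      if (dcol > 0) (nc - origin[[2L]]) / dcol
      else if (dcol < 0) (1 - origin[[2L]]) / dcol else Inf)
    if (tmax <= step) next
    rr <- seq(0, tmax, by = step)
    prow <- origin[[1L]] + rr * drow
    pcol <- origin[[2L]] + rr * dcol
    inm <- filled[cbind(pmin(pmax(round(prow), 1L), nr),
                        pmin(pmax(round(pcol), 1L), nc))]
    exit <- which(!inm)[1L]
    if (is.na(exit) || exit == 1L) next
    rb <- rr[[exit - 1L]] # last in-mask sample
    sel <- rr > rb & rr <= rb + Lpx
    if (sum(sel) < 3L) next
    rs <- rr[sel]
    srow <- pmin(pmax(round(origin[[1L]] + rs * drow), 1L), nr)
    scol <- pmin(pmax(round(origin[[2L]] + rs * dcol), 1L), nc)
    inOther <- otherBodies[cbind(srow, scol)]
    if (any(inOther)) { # stop before entering a neighboring cell
      cut <- which(inOther)[[1L]] - 1L
      if (cut < 3L) next
      rs <- rs[seq_len(cut)]
    }
    ys <- bilinearInterp(px, origin[[1L]] + rs * drow,
                         origin[[2L]] + rs * dcol)
    n <- length(ys)
    if (n < 3L) next
    isMax <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] &
                      ys[2:(n - 1)] >= ys[3:n], FALSE)
    hits <- which(isMax & ys > thr)
    if (!length(hits)) next
    # outermost peak still rooted to the cell body
    rooted <- vapply(hits, function(h)
      mean(ys[seq_len(h)] >= rootThr) >= 0.5, logical(1))
    if (!any(rooted)) next
    i <- hits[[max(which(rooted))]]
    # sub-pixel refinement along the ray
    denom <- ys[[i - 1L]] - 2 * ys[[i]] + ys[[i + 1L]]
    delta <- if (denom < 0) 0.5 * (ys[[i - 1L]] - ys[[i + 1L]]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    rpk <- rs[[i]] + delta * step
    cand[[length(cand) + 1L]] <- c(theta = th, r = rpk,
                                   row = origin[[1L]] + rpk * drow,
                                   col = origin[[2L]] + rpk * dcol,
                                   y = ys[[i]], distUm = (rpk - rb) * ps)
  }
  if (!length(cand)) return(emptyTipTable())
  cm <- do.call(rbind, cand)
  ord <- order(cm[, "theta"])
  cm <- cm[ord, , drop = FALSE]
  k <- nrow(cm)

  # angular non-maximum suppression: a candidate with a brighter candidate
  # within the merge angle is a flank of that peak, not a tip of its own
  mergeA <- config$mergeAngleDeg * pi / 180
  keep <- vapply(seq_len(k), function(i) {
    near <- angleDiff(cm[, "theta"], cm[i, "theta"]) <= mergeA + 1e-12
    cm[i, "y"] >= max(cm[near, "y"])
  }, logical(1))
  cm <- cm[keep, , drop = FALSE]
  k <- nrow(cm)

  # chain-cluster around the circle: adjacent candidates join one cluster
  # when both the angular gap and the radial offset are small
  grp <- seq_len(k)
  if (k > 1L) {
    joins <- function(i, j) {
      angleDiff(cm[i, "theta"], cm[j, "theta"]) <= mergeA + 1e-12 &&
        abs(cm[i, "r"] - cm[j, "r"]) * ps <= config$mergeRadiusUm
    }
    for (i in 2:k) if (joins(i - 1L, i)) grp[i] <- grp[[i - 1L]]
    if (joins(k, 1L)) grp[grp == grp[[k]]] <- grp[[1L]]
  }
  reps <- vapply(split(seq_len(k), grp), function(ix)
    ix[[which.max(cm[ix, "y"])]], integer(1))
  cm <- cm[sort(reps), , drop = FALSE]
  data.frame(tip_row = cm[, "row"], tip_col = cm[, "col"],
             angle_rad = cm[, "theta"], distance_um = cm[, "distUm"],
             peak_intensity = cm[, "y"],
             cell_id = rep(cell@cellId, nrow(cm)), row.names = NULL)
}

#' Assign detected tips to their parent cells
#'
#' Each tip is registered to the cell whose boundary contour is nearest;
#' exact ties go to the smaller cell id. Tips farther than `maxLengthUm`
#' from every boundary are dropped (their number is reported in a message).
#'
#' @param tips tip table from [radialTipSearch] (rows from several cells
#'   may be concatenated).
#' @param cells list of [CellRecord-class].
#' @param maxLengthUm drop radius (um), default 15.
#' @return the tip table with `cell_id` re-assigned.
#' @export
registerTipsToCells <- function(tips, cells, maxLengthUm = 15) {
  stopIfNot(length(cells) >= 1L, "need at least one cell")
  if (nrow(tips) == 0L) return(tips)
  ps <- cells[[1L]]@pixelSizeUm
  dmat <- vapply(cells, function(cc) {
    b <- cc@boundary
    vapply(seq_len(nrow(tips)), function(i)
      sqrt(min((b[, 1L] - tips$tip_row[[i]])^2 +
               (b[, 2L] - tips$tip_col[[i]])^2)) * ps, numeric(1))
  }, numeric(nrow(tips)))
  dmat <- matrix(dmat, nrow = nrow(tips))
  ids <- vapply(cells, function(cc) cc@cellId, integer(1))
  best <- apply(dmat, 1L, function(d) {
    near <- which(d <= min(d) + 1e-9)
    near[[which.min(ids[near])]] # tie -> smaller cell id
  })
  tips$cell_id <- ids[best]
  keep <- apply(dmat, 1L, min) <= maxLengthUm
  if (any(!keep))
    message(sum(!keep), " tip(s) farther than maxLengthUm from every cell dropped")
  tips[keep, , drop = FALSE]
}

#' Summarize filopodium counts across cells
#'
#' Reports the percentage of all analyzed cells with at least one
#' filopodium and the mean count (with SEM) among the cells that have at
#' least one; `N` counts experiments, `n` counts cells. With zero positive
#' cells the mean is reported as 0 with `nPositive = 0`.
#'
#' @param counts integer vector of per-cell filopodium counts.
#' @param experiments optional replicate labels, one per cell.
#' @return list: percentWithFilopodia, meanCountPositive, semCountPositive,
#'   nPositive, N, n.
#' @examples
#' summarizeFilopodia(c(0, 0, 1, 3, 4))
#' @export
summarizeFilopodia <- function(counts, experiments = NULL) {
  stopIfNot(length(counts) >= 1L, "need at least one analyzed cell")
  stopIfNot(all(counts >= 0), "counts must be non-negative")
  pos <- counts[counts >= 1]
  m <- if (length(pos)) mean(pos) else 0
  s <- if (length(pos) > 1L) stats::sd(pos) / sqrt(length(pos)) else 0
  list(percentWithFilopodia = 100 * mean(counts >= 1),
       meanCountPositive = m, semCountPositive = s,
       nPositive = length(pos),
       N = if (is.null(experiments)) 1L else length(unique(experiments)),
       n = length(counts))
}
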