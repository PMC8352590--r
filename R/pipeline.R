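#' Default pipeline configuration
#'
#' All tunable parameters of the quantification pipeline with their
#' defaults: 0.8 um cortical band, 360 angular bins, Otsu thresholding with
#' a 0.5 um opening, the radial tip-search defaults, 5 spline knots and
#' ROUT at Q = 0.001.
#'
#' @return nested named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    pixel_size_um = 0.212,
    band_width_um = 0.8,
    n_bins = 360L,
    strict = TRUE,
    seed = 1L,
    output_dir = "cortexquant_run",
    segmentation = list(method = "otsu", value = NULL, body_open_um = 0.5,
                        nucleus_fraction = 0.5, nucleus_min_area_um2 = 2,
                        min_cell_area_um2 = 20, expression_min = NULL,
                        exclude_border = TRUE),
    tips = list(dtheta_deg = 1, max_length_um = 15, k_sigma = 4,
                merge_angle_deg = 5, merge_radius_um = 1),
    spline = list(n_knots = 5L),
    stats = list(rout_q = 0.001,
                 star_cuts = c(0.05, 0.01, 0.001, 0.0001),
                 posthoc = "tukey", control = NULL),
    simulate = NULL,
    inputs = NULL
  )
}

mergeConfig <- function(base, override, path = "", violations) {
  for (key in names(override)) {
    if (!key %in% names(base)) {
      violations$msgs <- c(violations$msgs,
                           sprintf("unknown key: %s%s", path, key))
      next
    }
    bv <- base[[key]]
    ov <- override[[key]]
    if (is.list(bv) && !is.null(bv) && !key %in% c("simulate", "inputs")) {
      if (!is.list(ov)) {
        violations$msgs <- c(violations$msgs,
                             sprintf("%s%s must be a section", path, key))
        next
      }
      base[[key]] <- mergeConfig(bv, ov, paste0(path, key, "."), violations)
    } else {
      base[key] <- list(ov)
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list, merges it over
#' [defaultConfig], rejects unknown keys, and range-checks every value,
#' reporting all violations at once before any computation or I/O.
#'
#' @param config YAML path, named list of overrides, or `NULL` for pure
#'   defaults.
#' @return the fully resolved configuration list.
#' @examples
#' cfg <- validateConfig(list(band_width_um = 0.8))
#' cfg$n_bins
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    stopIfNot(file.exists(config), sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopIfNot(is.null(config) || is.list(config),
            "config must be a file path, a list, or NULL")
  violations <- new.env()
  violations$msgs <- character()
  cfg <- mergeConfig(defaultConfig(), config %||% list(), "", violations)

  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  check <- function(cond, msg) {
    if (!isTRUE(cond)) violations$msgs <- c(violations$msgs, msg)
  }
  check(num(cfg$pixel_size_um) && cfg$pixel_size_um > 0,
        "pixel_size_um must be a positive number")
  check(num(cfg$band_width_um) && cfg$band_width_um > 0,
        "band_width_um must be a positive number")
  check(num(cfg$n_bins) && cfg$n_bins >= 8,
        "n_bins must be a number >= 8")
  check(num(cfg$seed), "seed must be a number")
  check(is.logical(cfg$strict), "strict must be logical")
  check(cfg$segmentation$method %in% c("otsu", "fixed"),
        "segmentation.method must be 'otsu' or 'fixed'")
  check(num(cfg$segmentation$body_open_um) && cfg$segmentation$body_open_um >= 0,
        "segmentation.body_open_um must be >= 0")
  check(num(cfg$segmentation$nucleus_fraction) &&
          cfg$segmentation$nucleus_fraction > 0 &&
          cfg$segmentation$nucleus_fraction < 1,
        "segmentation.nucleus_fraction must be in (0, 1)")
  check(num(cfg$tips$dtheta_deg) && cfg$tips$dtheta_deg > 0,
        "tips.dtheta_deg must be > 0")
  check(num(cfg$tips$max_length_um) && cfg$tips$max_length_um > 0,
        "tips.max_length_um must be > 0")
  check(num(cfg$tips$k_sigma) && cfg$tips$k_sigma >= 0,
        "tips.k_sigma must be >= 0")
  check(num(cfg$spline$n_knots) && cfg$spline$n_knots >= 3,
        "spline.n_knots must be >= 3")
  check(num(cfg$stats$rout_q) && cfg$stats$rout_q > 0 && cfg$stats$rout_q < 1,
        "stats.rout_q must be in (0, 1)")
  check(is.numeric(cfg$stats$star_cuts) && length(cfg$stats$star_cuts) == 4L,
        "stats.star_cuts must be four cutpoints")
  check(cfg$stats$posthoc %in% c("tukey", "dunnett"),
        "stats.posthoc must be 'tukey' or 'dunnett'")
  if (length(violations$msgs))
    stop("invalid configuration:\n  ",
         paste(violations$msgs, collapse = "\n  "), call. = FALSE)
  cfg$n_bins <- as.integer(cfg$n_bins)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sceneParamsFromList <- function(overrides, pixelSizeUm, seed) {
  args <- overrides %||% list()
  args$pixelSizeUm <- args$pixelSizeUm %||% pixelSizeUm
  args$seed <- seed
  do.call(SceneParams, args)
}

quantifyMicrograph <- function(img, cfg, fieldId, experimentId,
                               condition = "default") {
  segCfg <- segmentationConfig(
    method = cfg$segmentation$method, value = cfg$segmentation$value,
    bodyOpenUm = cfg$segmentation$body_open_um,
    nucleusFraction = cfg$segmentation$nucleus_fraction,
    nucleusMinAreaUm2 = cfg$segmentation$nucleus_min_area_um2,
    minCellAreaUm2 = cfg$segmentation$min_cell_area_um2,
    expressionMin = cfg$segmentation$expression_min,
    excludeBorder = cfg$segmentation$exclude_border)
  tipCfg <- tipSearchConfig(
    dthetaDeg = cfg$tips$dtheta_deg, maxLengthUm = cfg$tips$max_length_um,
    kSigma = cfg$tips$k_sigma, mergeAngleDeg = cfg$tips$merge_angle_deg,
    mergeRadiusUm = cfg$tips$merge_radius_um)
  cells <- segmentCells(img, segCfg)
  rows <- list()
  tipRows <- list()
  for (cc in cells) {
    m <- cellMetrics(img, cc, bandWidthUm = cfg$band_width_um,
                     nBins = cfg$n_bins, tipConfig = tipCfg,
                     allCells = cells)
    m <- cbind(data.frame(field_id = fieldId, condition = condition,
                          experiment_id = experimentId), m)
    rows[[length(rows) + 1L]] <- m
    tips <- radialTipSearch(img, cc, tipCfg, allCells = cells)
    if (nrow(tips) > 0L) {
      tips$field_id <- fieldId
      tipRows[[length(tipRows) + 1L]] <- tips
    }
  }
  list(metrics = do.call(rbind, rows), tips = do.call(rbind, tipRows))
}

#' Run the full quantification pipeline
#'
#' Executes simulate/read, maximum projection, segmentation, cortical
#' partition, per-cell metrics, tip search, condition summaries and group
#' statistics, and writes five artifacts to the output directory:
#' `per_cell.csv` (+ JSON sidecar), `tips.csv`, `summary.json`,
#' `comparisons.csv` and `manifest.json`. Identical configuration and seed
#' reproduce identical CSV bytes.
#'
#' A simulation run is described by `config$simulate`, a list with
#' `conditions` (each: `name`, `n_cells`, and optional `params` overriding
#' [SceneParams] fields) and optionally `n_experiments` (default 3,
#' round-robin assignment of cells to pseudo-replicates). A file run lists
#' `config$inputs`: entries with `path` and optional `condition`,
#' `experiment`, `channel` (sidecar-less TIFFs use `pixel_size_um`).
#'
#' @param config configuration accepted by [validateConfig].
#' @return the output directory, invisibly; its `manifest.json` records
#'   config hash, seed, package version and per-stage counts.
#' @export
runPipeline <- function(config = NULL) {
  cfg <- validateConfig(config)
  stopIfNot(!is.null(cfg$simulate) || !is.null(cfg$inputs),
            "config needs a 'simulate' spec or an 'inputs' list")
  outDir <- cfg$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  allMetrics <- list()
  allTips <- list()

  if (!is.null(cfg$simulate)) {
    conds <- cfg$simulate$conditions
    stopIfNot(is.list(conds) && length(conds) >= 1L,
              "simulate.conditions must be a non-empty list")
    nExp <- cfg$simulate$n_experiments %||% 3L
    seeds <- childSeeds(cfg$seed, sum(vapply(conds, function(cn)
      as.integer(cn$n_cells), integer(1))))
    si <- 0L
    for (cn in conds) {
      for (i in seq_len(cn$n_cells)) {
        si <- si + 1L
        params <- sceneParamsFromList(cn$params, cfg$pixel_size_um,
                                      seeds[[si]])
        sc <- makeCellScene(params)
        img <- maxProject(sc$stack)
        res <- quantifyMicrograph(
          img, cfg, fieldId = sprintf("%s_%03d", cn$name, i),
          experimentId = sprintf("e%d", (i - 1L) %% nExp + 1L),
          condition = cn$name)
        if (!is.null(res$metrics))
          allMetrics[[length(allMetrics) + 1L]] <- res$metrics
        if (!is.null(res$tips)) allTips[[length(allTips) + 1L]] <- res$tips
      }
    }
  } else {
    for (inp in cfg$inputs) {
      stacks <- readStack(inp$path, pixelSizeUm = inp$pixel_size_um,
                          strict = cfg$strict)
      img <- maxProject(stacks[[1L]])
      res <- quantifyMicrograph(
        img, cfg, fieldId = basename(inp$path),
        experimentId = inp$experiment %||% "e1",
        condition = inp$condition %||% "default")
      if (!is.null(res$metrics))
        allMetrics[[length(allMetrics) + 1L]] <- res$metrics
      if (!is.null(res$tips)) allTips[[length(allTips) + 1L]] <- res$tips
    }
  }

  metrics <- do.call(rbind, allMetrics)
  stopIfNot(!is.null(metrics) && nrow(metrics) > 0L,
            "no analyzable cells produced by this run")
  tips <- if (length(allTips)) do.call(rbind, allTips) else emptyTipTable()

  writeResults(metrics, file.path(outDir, "per_cell.csv"), config = cfg)
  utils::write.csv(metrics, file.path(outDir, "per_cell_full.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(tips, file.path(outDir, "tips.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")

  summaryTab <- buildSummaryTable(metrics, routQ = cfg$stats$rout_q)
  jsonlite::write_json(summaryTab, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  okRatio <- is.finite(metrics$cortex_cyto_ratio)
  grpSizes <- table(metrics$condition[okRatio])
  if (length(grpSizes) >= 2L && all(grpSizes >= 2L)) {
    ct <- oneWayAnova(metrics$cortex_cyto_ratio[okRatio],
                      metrics$condition[okRatio],
                      posthoc = cfg$stats$posthoc,
                      control = cfg$stats$control,
                      starCuts = cfg$stats$star_cuts)
    utils::write.csv(ct$pairwise, file.path(outDir, "comparisons.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    utils::write.csv(data.frame(comparison = character(0),
                                estimate = numeric(0), p_adj = numeric(0),
                                stars = character(0)),
                     file.path(outDir, "comparisons.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }

  manifest <- list(
    config_hash = objectHash(cfg), seed = cfg$seed,
    version = as.character(utils::packageVersion("CortexQuant")),
    n_cells = nrow(metrics), n_tips = nrow(tips),
    n_conditions = length(unique(metrics$condition)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
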