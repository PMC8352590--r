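starCode <- function(p, cuts = c(0.05, 0.01, 0.001, 0.0001)) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < cuts[[4L]]) "****"
    else if (pp < cuts[[3L]]) "***"
    else if (pp < cuts[[2L]]) "**"
    else if (pp < cuts[[1L]]) "*"
    else "ns"
  }, character(1))
}

#' ROUT-style robust outlier identification (constant model)
#'
#' Identifies "definite" outliers in a univariate sample by combining a
#' robust fit with a false-discovery-rate test: the robust location is the
#' median; the robust scale (RSDR) is the 68.27th percentile of the
#' absolute residuals with the small-sample correction `N / (N - 1)` (one
#' fitted parameter); each point's t-like statistic
#' `|residual| / RSDR` is converted to a two-sided p-value on `N - 1`
#' degrees of freedom, and points rejected by a Benjamini-Hochberg step-up
#' at rate `Q` are flagged. This is the published outlier-removal method
#' reduced to the constant-model case appropriate for a univariate metric;
#' `Q = 0.001` (0.1%) flags only definite outliers.
#'
#' Samples below 10 points are returned unfiltered with a warning; samples
#' with zero robust scale flag nothing.
#'
#' @param values numeric vector.
#' @param Q maximum desired false-discovery rate, default 0.001.
#' @return list: `values` (retained), `outlier` (logical flags, one per
#'   input), `Q`.
#' @examples
#' routFilter(c(rnorm(100), 50))$outlier |> which()
#' @export
routFilter <- function(values, Q = 0.001) {
  stopIfNot(is.numeric(values) && all(is.finite(values)),
            "values must be finite numerics")
  stopIfNot(Q > 0 && Q < 1, "Q must be in (0, 1)")
  n <- length(values)
  flags <- rep(FALSE, n)
  if (n < 10L) {
    warning("fewer than 10 values: no outlier filtering applied",
            call. = FALSE)
    return(list(values = values, outlier = flags, Q = Q))
  }
  resid <- values - stats::median(values)
  p68 <- stats::quantile(abs(resid), 0.6827, names = FALSE)
  rsdr <- p68 * n / (n - 1)
  if (rsdr == 0)
    return(list(values = values, outlier = flags, Q = Q))
  tstat <- abs(resid) / rsdr
  p <- 2 * stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  ord <- order(p)
  below <- p[ord] <= Q * seq_len(n) / n
  if (any(below)) {
    kmax <- max(which(below))
    flags[ord[seq_len(kmax)]] <- TRUE
  }
  list(values = values[!flags], outlier = flags, Q = Q)
}

#' One-way ANOVA with Tukey or Dunnett comparisons
#'
#' Classical fixed-effects one-way ANOVA on cell-level values, followed by
#' Tukey HSD over all pairs or Dunnett's comparisons against a named
#' control group. Significance codes use the conventional cutpoints
#' 0.05 / 0.01 / 0.001 / 0.0001 (`ns`, `*`, `**`, `***`, `****`).
#'
#' @param values numeric vector of per-cell values.
#' @param groups group labels (factor or character), one per value.
#' @param posthoc `"tukey"` (default) or `"dunnett"`.
#' @param control control group name (required for Dunnett).
#' @param starCuts p-value cutpoints for the significance codes.
#' @return object of class `"ComparisonTable"`: list with `test`, `F`,
#'   `df` (between, within), `p`, and `pairwise` (data.frame: comparison,
#'   estimate, p_adj, stars).
#' @examples
#' oneWayAnova(c(rnorm(10), rnorm(10, 2)), rep(c("a", "b"), each = 10))
#' @export
oneWayAnova <- function(values, groups, posthoc = c("tukey", "dunnett"),
                        control = NULL,
                        starCuts = c(0.05, 0.01, 0.001, 0.0001)) {
  posthoc <- match.arg(posthoc)
  g <- factor(groups)
  stopIfNot(nlevels(g) >= 2L, "need at least two groups")
  stopIfNot(all(table(g) >= 2L), "each group needs at least two values")
  if (all(tapply(values, g, stats::var) == 0))
    stop("zero within-group variance in every group: F undefined",
         call. = FALSE)
  if (posthoc == "dunnett") {
    stopIfNot(!is.null(control) && control %in% levels(g),
              "Dunnett comparisons need a control group present in 'groups'")
    g <- stats::relevel(g, ref = control)
  }
  dat <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1L]]
  Fv <- an[["F value"]][[1L]]
  pv <- an[["Pr(>F)"]][[1L]]
  dfs <- as.integer(an[["Df"]])

  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                     p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    pw <- data.frame(comparison = names(sm$test$coefficients),
                     estimate = unname(sm$test$coefficients),
                     p_adj = unname(sm$test$pvalues), row.names = NULL)
  }
  pw$stars <- starCode(pw$p_adj, starCuts)
  structure(list(test = sprintf("one-way ANOVA + %s", posthoc), F = Fv,
                 df = dfs, p = pv, pairwise = pw),
            class = "ComparisonTable")
}

#' Student's t-test for two groups
#'
#' Two-sided pooled-variance ("Student's") t-test by default, with a
#' Welch option.
#'
#' @param groupA,groupB numeric vectors (each n >= 2).
#' @param varEqual pooled-variance form (default `TRUE`).
#' @return `"ComparisonTable"` with `t`, `df`, `p` and a one-row
#'   `pairwise` table.
#' @export
studentsT <- function(groupA, groupB, varEqual = TRUE) {
  stopIfNot(length(groupA) >= 2L && length(groupB) >= 2L,
            "each group needs at least two values")
  if (varEqual && stats::var(c(groupA - mean(groupA),
                               groupB - mean(groupB))) == 0)
    stop("zero pooled variance: t undefined", call. = FALSE)
  tt <- stats::t.test(groupA, groupB, var.equal = varEqual)
  pw <- data.frame(comparison = "A-B",
                   estimate = mean(groupA) - mean(groupB),
                   p_adj = tt$p.value, stars = starCode(tt$p.value))
  structure(list(test = if (varEqual) "Student's t" else "Welch t",
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, pairwise = pw),
            class = "ComparisonTable")
}

#' @export
print.ComparisonTable <- function(x, ...) {
  cat(x$test, "\n")
  if (!is.null(x[["F"]]))
    cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x[["df"]][[1L]],
                x[["df"]][[2L]], x[["F"]], x[["p"]]))
  if (!is.null(x[["t"]]))
    cat(sprintf("  t(%.1f) = %.4g, p = %.4g\n", x[["df"]], x[["t"]],
                x[["p"]]))
  print(x$pairwise, ...)
  invisible(x)
}

#' Per-experiment (replicate) means
#'
#' Mean of the cell-level values per (group, experiment), the quantities
#' shown as replicate symbols on superplot-style graphs. Statistical tests
#' stay on the full cell-level data; both the unweighted grand mean of the
#' experiment means and the pooled cell-level mean are reported per group
#' (they differ under unequal per-experiment n).
#'
#' @param values numeric per-cell values.
#' @param groups group labels.
#' @param experiments replicate labels.
#' @return list: `experimentMeans` (data.frame group, experiment, n,
#'   mean), `groupSummary` (data.frame group, mean_of_experiment_means,
#'   pooled_mean, n_cells, n_experiments).
#' @export
experimentMeans <- function(values, groups, experiments) {
  stopIfNot(length(values) == length(groups) &&
              length(values) == length(experiments),
            "values, groups and experiments must be the same length")
  d <- data.frame(y = values, g = factor(groups), e = factor(experiments))
  em <- stats::aggregate(y ~ g + e, data = d, FUN = mean)
  nn <- stats::aggregate(y ~ g + e, data = d, FUN = length)
  em <- data.frame(group = as.character(em$g),
                   experiment = as.character(em$e), n = nn$y, mean = em$y)
  em <- em[order(em$group, em$experiment), , drop = FALSE]
  gs <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$g), function(ix) {
    sub <- d[ix, , drop = FALSE]
    ems <- em$mean[em$group == as.character(sub$g[[1L]])]
    data.frame(group = as.character(sub$g[[1L]]),
               mean_of_experiment_means = mean(ems),
               pooled_mean = mean(sub$y), n_cells = nrow(sub),
               n_experiments = length(ems))
  }))
  rownames(gs) <- NULL
  list(experimentMeans = em, groupSummary = gs)
}

#' Condition-level summary table
#'
#' Builds the summary rows reported for each condition: the percentage of
#' cells with at least one filopodium, the mean filopodium count (with
#' SEM) among positive cells, the mean cortex:cytoplasm ratio (with SEM)
#' after ROUT outlier exclusion applied to the ratio only, and the number
#' of experiments (N) and cells (n).
#'
#' @param metrics data.frame with columns `condition`, `experiment_id`,
#'   `filopodia_count`, `cortex_cyto_ratio` (one row per analyzed cell).
#' @param routQ FDR for the ratio outlier filter, default 0.001; `NULL`
#'   disables filtering.
#' @return data.frame, one row per condition: condition,
#'   percent_with_filopodia, filopodia_mean, filopodia_sem, ratio_mean,
#'   ratio_sem, n_ratio_outliers, N, n.
#' @export
buildSummaryTable <- function(metrics, routQ = 0.001) {
  need <- c("condition", "experiment_id", "filopodia_count",
            "cortex_cyto_ratio")
  missing <- setdiff(need, names(metrics))
  if (length(missing))
    stop("metrics missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(metrics, metrics$condition), function(sub) {
    if (nrow(sub) == 0L) return(NULL)
    fs <- summarizeFilopodia(sub$filopodia_count, sub$experiment_id)
    ratios <- sub$cortex_cyto_ratio[is.finite(sub$cortex_cyto_ratio)]
    nOut <- 0L
    if (!is.null(routQ) && length(ratios) >= 10L) {
      rf <- routFilter(ratios, Q = routQ)
      nOut <- sum(rf$outlier)
      ratios <- rf$values
    }
    data.frame(condition = sub$condition[[1L]],
               percent_with_filopodia = fs$percentWithFilopodia,
               filopodia_mean = fs$meanCountPositive,
               filopodia_sem = fs$semCountPositive,
               ratio_mean = mean(ratios),
               ratio_sem = stats::sd(ratios) / sqrt(length(ratios)),
               n_ratio_outliers = nOut, N = fs$N, n = fs$n)
  })
  empty <- vapply(out, is.null, logical(1))
  if (any(empty))
    warning("conditions with zero cells omitted: ",
            paste(names(out)[empty], collapse = ", "), call. = FALSE)
  res <- do.call(rbind, out[!empty])
  rownames(res) <- NULL
  res
}
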