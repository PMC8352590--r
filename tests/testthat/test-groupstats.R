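test_that("ROUT flags gross contaminants but spares clean samples", {
  allSame <- routFilter(rep(3.2, 20))
  expect_false(any(allSame$outlier))
  expect_warning(small <- routFilter(rnorm(5)), "fewer than 10")
  expect_false(any(small$outlier))

  caught <- 0L
  for (s in 1:25) {
    x <- withr::with_seed(400 + s, c(rnorm(100), 50))
    rf <- routFilter(x, Q = 0.001)
    if (rf$outlier[101] && sum(rf$outlier) == 1L) caught <- caught + 1L
  }
  expect_gte(caught, 24L)

  frac <- vapply(1:25, function(s) {
    mean(routFilter(withr::with_seed(500 + s, rnorm(1000)),
                    Q = 0.001)$outlier)
  }, numeric(1))
  expect_lte(mean(frac), 0.005)
})

test_that("one-way ANOVA reduces to t-squared for two groups", {
  a <- withr::with_seed(1, rnorm(12, 5, 2))
  b <- withr::with_seed(2, rnorm(15, 6, 2))
  an <- oneWayAnova(c(a, b), rep(c("a", "b"), c(12, 15)))
  tt <- studentsT(a, b)
  expect_equal(an[["F"]], tt[["t"]]^2, tolerance = 1e-10)
  expect_equal(an[["p"]], tt[["p"]], tolerance = 1e-10)
})

test_that("ANOVA F matches an independent sum-of-squares computation", {
  vals <- c(4.1, 5.2, 3.9, 4.8, 5.0,
            6.3, 5.9, 6.8, 6.1, 6.4,
            4.9, 5.1, 5.4, 4.7, 5.3)
  grp <- rep(c("g1", "g2", "g3"), each = 5)
  an <- oneWayAnova(vals, grp)
  # textbook sums of squares, written out from scratch
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(5 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  Fo <- (ssb / 2) / (ssw / 12)
  expect_equal(an[["F"]], Fo, tolerance = 1e-10)
  expect_equal(an[["p"]], stats::pf(Fo, 2, 12, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_identical(an[["df"]], c(2L, 12L))
})

test_that("ANOVA p agrees with a label-permutation null on a fixture", {
  vals <- withr::with_seed(10, c(rnorm(8), rnorm(8, 0.9), rnorm(8, 0.3)))
  grp <- rep(c("a", "b", "c"), each = 8)
  an <- oneWayAnova(vals, grp)
  fstat <- function(v) {
    m <- tapply(v, grp, mean); g <- mean(v)
    (sum(8 * (m - g)^2) / 2) / (sum((v - m[grp])^2) / 21)
  }
  B <- 2000L
  perms <- withr::with_seed(11, vapply(seq_len(B), function(i)
    fstat(sample(vals)), numeric(1)))
  pPerm <- (1 + sum(perms >= an[["F"]])) / (B + 1)
  mcErr <- 3 * sqrt(pPerm * (1 - pPerm) / B)
  expect_lt(abs(an[["p"]] - pPerm), mcErr + 0.01)
})

test_that("post hoc tables respect adjustment and comparison scope", {
  vals <- withr::with_seed(12, c(rnorm(10), rnorm(10, 1), rnorm(10, 2)))
  grp <- rep(c("wt", "m1", "m2"), each = 10)
  tk <- oneWayAnova(vals, grp, posthoc = "tukey")
  expect_identical(nrow(tk$pairwise), 3L)
  # Tukey-adjusted p >= raw pairwise p (same pooled error term) per pair
  mse <- sum(unlist(tapply(vals, grp, function(v) (v - mean(v))^2))) / 27
  for (i in seq_len(3)) {
    gg <- strsplit(tk$pairwise$comparison[i], "-")[[1]]
    tRaw <- abs(mean(vals[grp == gg[1]]) - mean(vals[grp == gg[2]])) /
      sqrt(mse * (1 / 10 + 1 / 10))
    raw <- 2 * stats::pt(tRaw, 27, lower.tail = FALSE)
    expect_gte(tk$pairwise$p_adj[i] + 1e-12, raw)
  }
  dn <- oneWayAnova(vals, grp, posthoc = "dunnett", control = "wt")
  expect_identical(nrow(dn$pairwise), 2L)
  expect_true(all(grepl("wt", dn$pairwise$comparison)))
  expect_true(all(c("ns", "*", "**", "***", "****") %in%
                    c(tk$pairwise$stars, dn$pairwise$stars, "ns", "*",
                      "**", "***", "****")))
  expect_error(oneWayAnova(rep(c(1, 2), each = 5), rep(c("a", "b"), each = 5)),
               "zero within-group variance")
})

test_that("Student's t behaves at the exact and shifted limits", {
  x <- c(1.2, 3.4, 2.2, 4.8)
  same <- studentsT(x, x)
  expect_equal(same[["t"]], 0, tolerance = 1e-12)
  expect_equal(same[["p"]], 1, tolerance = 1e-12)
  shift <- studentsT(x + 2, x)
  expect_gt(shift[["t"]], 0)
  down <- studentsT(x - 2, x)
  expect_lt(down[["t"]], 0)
  expect_error(studentsT(c(1, 1, 1), c(1, 1, 1)), "zero pooled variance")
  # permutation cross-check
  a <- withr::with_seed(13, rnorm(10))
  b <- withr::with_seed(14, rnorm(10, 0.8))
  tt <- studentsT(a, b)
  pool <- c(a, b)
  B <- 2000L
  perms <- withr::with_seed(15, vapply(seq_len(B), function(i) {
    s <- sample(20L, 10L)
    mean(pool[s]) - mean(pool[-s])
  }, numeric(1)))
  obs <- mean(a) - mean(b)
  pPerm <- (1 + sum(abs(perms) >= abs(obs))) / (B + 1)
  expect_lt(abs(tt[["p"]] - pPerm), 3 * sqrt(pPerm * (1 - pPerm) / B) + 0.01)
})

test_that("experiment means echo construction and expose weighting", {
  one <- experimentMeans(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3),
                         rep("e1", 6))
  expect_equal(one$groupSummary$mean_of_experiment_means, c(2, 8))
  expect_equal(one$groupSummary$pooled_mean, c(2, 8))

  vals <- c(rep(1, 2), rep(5, 8)) # e1 mean 1 (n=2), e2 mean 5 (n=8)
  em <- experimentMeans(vals, rep("g", 10), rep(c("e1", "e2"), c(2, 8)))
  expect_equal(em$experimentMeans$mean, c(1, 5))
  expect_equal(em$groupSummary$mean_of_experiment_means, 3)
  expect_equal(em$groupSummary$pooled_mean, 4.2)
})

test_that("summary tables reproduce hand arithmetic, with SEM = SD/sqrt(n)", {
  metrics <- data.frame(
    condition = "ctrl", experiment_id = rep(c("e1", "e2"), c(3, 2)),
    filopodia_count = c(0, 0, 1, 3, 4),
    cortex_cyto_ratio = c(1.0, 1.1, 1.2, 1.3, 1.4))
  tab <- buildSummaryTable(metrics, routQ = NULL)
  expect_equal(tab$percent_with_filopodia, 60)
  expect_equal(tab$filopodia_mean, 8 / 3)
  expect_equal(tab$filopodia_sem, stats::sd(c(1, 3, 4)) / sqrt(3))
  expect_equal(tab$ratio_mean, 1.2)
  expect_equal(tab$ratio_sem, stats::sd(metrics$cortex_cyto_ratio) / sqrt(5))
  expect_identical(tab$N, 2L)
  expect_identical(tab$n, 5L)

  # an outlier ratio is removed by the ROUT filter before averaging
  m2 <- data.frame(condition = "x", experiment_id = "e1",
                   filopodia_count = 0,
                   cortex_cyto_ratio = withr::with_seed(16,
                     c(rnorm(30, 1.2, 0.05), 9)))
  tab2 <- buildSummaryTable(m2, routQ = 0.001)
  expect_identical(tab2$n_ratio_outliers, 1L)
  expect_lt(tab2$ratio_mean, 1.5)

  m3 <- metrics
  m3$condition <- factor("ctrl", levels = c("ctrl", "ghost"))
  expect_warning(buildSummaryTable(m3, routQ = NULL), "ghost")
})
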