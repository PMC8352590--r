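test_that("cytofluorogram r hits the exact limits and the simulated rho", {
  sc <- makeCellScene(SceneParams(seed = 71))
  img <- maxProject(sc$stack)
  mask <- sc$truth@cells[[1]]$filledMask
  same <- cytofluorogram(img, img, mask)
  expect_equal(same@r, 1, tolerance = 1e-12)
  inv <- Micrograph(max(pixels(img)) - pixels(img), img@pixelSizeUm)
  expect_equal(cytofluorogram(img, inv, mask)@r, -1, tolerance = 1e-12)

  p <- SceneParams(imageShape = c(420L, 420L), cellRadiusUm = 40,
                   nucleusRadiusUm = 6, nucleusOffsetUm = 4, seed = 72)
  tc <- makeTwoChannelScene(p, 0.8)
  cf <- cytofluorogram(tc$chA, tc$chB, tc$truth@cells[[1]]$filledMask)
  expect_gte(cf@n, 1e5)
  expect_equal(cf@r, 0.8, tolerance = 0.02)
  # affine rescaling of either channel leaves r unchanged
  g <- Micrograph(pixels(tc$chB) * 4.2 + 7, tc$chB@pixelSizeUm)
  expect_equal(cytofluorogram(tc$chA, g, tc$truth@cells[[1]]$filledMask)@r,
               cf@r, tolerance = 1e-10)
})

test_that("degenerate cytofluorogram inputs are rejected or flagged", {
  a <- Micrograph(matrix(runif(400), 20), 0.2)
  flat <- Micrograph(matrix(1, 20, 20), 0.2)
  mask <- matrix(TRUE, 20, 20)
  expect_error(cytofluorogram(a, flat, mask), "constant")
  small <- matrix(FALSE, 20, 20); small[1:5, 1:5] <- TRUE
  expect_true("small_mask" %in% cytofluorogram(a, a, small)@flags)
  h <- cytofluorogramHistogram(cytofluorogram(a, a, mask), nbins = 16L)
  expect_identical(sum(h$count), 400L)
})

test_that("linescan extraction is exact on rasters and finds step edges", {
  m <- withr::with_seed(2, matrix(runif(40 * 40, 0, 10), 40))
  img <- Micrograph(m, 0.212)
  ls <- extractLinescan(img, c(7, 3), c(7, 30), widthPx = 1L)
  expect_identical(ls$intensity, m[7, 3:30])
  flat <- extractLinescan(Micrograph(matrix(5, 30, 30), 0.2),
                          c(4, 4), c(25, 22))
  expect_true(all(abs(flat$intensity - 5) < 1e-12))
  expect_error(extractLinescan(img, c(5, 5), c(5, 5)), "zero-length")
  # step edge at column 20.5: transition located within 2 px
  stepm <- matrix(10, 40, 40); stepm[, 21:40] <- 100
  lsS <- extractLinescan(Micrograph(stepm, 0.212), c(20, 5), c(20, 36))
  mid <- (10 + 100) / 2
  crossPx <- 5 + (which(lsS$intensity >= mid)[1] - 1)
  expect_lt(abs(crossPx - 20.5), 2)
})

test_that("longest-axis profiles align with the principal axis", {
  # 2:1 ellipse rotated by 30 degrees: orientation within 3 degrees
  n <- 120L
  ang <- 30 * pi / 180
  rowg <- matrix(seq_len(n), n, n); colg <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- rowg - 60.5; dx <- colg - 60.5
  u <- dx * cos(ang) + dy * sin(ang)
  v <- -dx * sin(ang) + dy * cos(ang)
  mask <- (u / 40)^2 + (v / 20)^2 <= 1
  cell <- maskCellRecord(mask, 0.212)
  img <- Micrograph(matrix(50, n, n) + 50 * mask, 0.212)
  prof <- longestAxisProfile(img, cell)
  got <- attr(prof, "axis_angle_rad") %% pi
  expect_lt(min(abs(got - ang), pi - abs(got - ang)), 3 * pi / 180)
  # circle: any diameter; length within 2% of the diameter at zero margin
  circ <- (dy^2 + dx^2) <= 40^2
  cellC <- maskCellRecord(circ, 0.212)
  profC <- longestAxisProfile(Micrograph(matrix(1, n, n) + circ, 0.212),
                              cellC, marginUm = 0)
  expect_true("near_circular" %in% attr(profC, "flags"))
  expect_equal(max(profC$position_um), 80 * 0.212, tolerance = 0.02)
})

test_that("cortically enriched cells show two peripheral peaks on the long axis", {
  sc <- makeCellScene(noiselessParams(enrichment = 1.8, seed = 73))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  prof <- longestAxisProfile(img, cell, marginUm = 1)
  y <- prof$intensity
  n <- length(y)
  peaks <- which(c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                          y[2:(n - 1)] >= y[3:n], FALSE) & y > 120)
  expect_gte(length(peaks), 2L)
  # outermost peaks flank a lower interior plateau near the band center
  interior <- y[(min(peaks) + 5):(max(peaks) - 5)]
  expect_lt(stats::median(interior), max(y[peaks]))
})

test_that("profile normalization is exact, order-preserving and idempotent", {
  expect_equal(normalizeProfile(c(2, 4, 6)), c(0, 0.5, 1))
  p <- data.frame(position_um = 1:5, intensity = c(3, 9, 5, 7, 4))
  np <- normalizeProfile(p)
  expect_equal(range(np$intensity), c(0, 1))
  expect_identical(order(np$intensity), order(p$intensity))
  expect_equal(normalizeProfile(np), np)
  expect_error(normalizeProfile(rep(2, 5)), "constant")
})

test_that("spline averaging recovers the generating curve", {
  xg <- seq(0, 1, length.out = 100)
  sig <- function(x) 1 / (1 + exp(-(x - 0.5) / 0.1))
  profs <- withr::with_seed(5, lapply(1:10, function(i)
    data.frame(position_um = xg,
               intensity = sig(xg) + rnorm(100, 0, 0.05))))
  ss <- averageProfilesSpline(profs, nKnots = 5L)
  expect_lt(sqrt(mean((ss$mean - sig(ss$grid))^2)), 0.03)
  expect_equal(ss$sem, ss$sd / sqrt(10), tolerance = 1e-15)
  # mean stays inside the pointwise envelope of the inputs
  interp <- sapply(profs, function(p)
    stats::approx(p$position_um, p$intensity, xout = ss$grid)$y)
  expect_true(all(ss$mean >= apply(interp, 1, min) - 1e-9))
  expect_true(all(ss$mean <= apply(interp, 1, max) + 1e-9))
  # order-invariant and exact on identical profiles
  ssPerm <- averageProfilesSpline(rev(profs), nKnots = 5L)
  expect_equal(ssPerm$mean, ss$mean, tolerance = 1e-12)
  gentle <- function(x) 1 / (1 + exp(-(x - 0.5) / 0.15))
  same <- lapply(1:10, function(i)
    data.frame(position_um = xg, intensity = gentle(xg)))
  ssSame <- averageProfilesSpline(same)
  expect_lt(max(abs(ssSame$mean - gentle(ssSame$grid))), 0.01)
  expect_error(averageProfilesSpline(profs, nKnots = 2L), "nKnots")
  far <- list(data.frame(position_um = 0:10, intensity = runif(11)),
              data.frame(position_um = 20:30, intensity = runif(11)))
  expect_error(averageProfilesSpline(far), "overlap")
})

test_that("pseudopod costaining correlation behaves under known couplings", {
  xg <- seq(0, 1, length.out = 100)
  sig <- function(x) 1 / (1 + exp(-(x - 0.5) / 0.12))
  profsA <- withr::with_seed(6, lapply(1:20, function(i)
    data.frame(position_um = xg,
               intensity = sig(xg) + rnorm(100, 0, 0.05))))
  dup <- pseudopodCostainingCorrelation(profsA, profsA)
  expect_true(all(abs(dup$perLineR - 1) < 1e-12))
  shuf <- withr::with_seed(7, lapply(profsA, function(p) {
    p$intensity <- sample(p$intensity); p
  }))
  expect_lt(abs(pseudopodCostainingCorrelation(profsA, shuf)$meanR), 0.1)
  profsB <- withr::with_seed(8, lapply(1:20, function(i)
    data.frame(position_um = xg,
               intensity = sig(xg) + rnorm(100, 0, 0.05))))
  expect_gt(pseudopodCostainingCorrelation(profsA, profsB)$meanR, 0.9)
  expect_error(pseudopodCostainingCorrelation(profsA, profsB[1:3]),
               "paired")
})
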