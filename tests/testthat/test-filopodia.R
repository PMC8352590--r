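# Draw a disk cell with hand-placed filopodia (shaft + Gaussian tip
# punctum) at exact angles, bypassing the generator's random placement.
drawnFilopodiaImage <- function(angles, radiusUm = 8, lengthUm = 3,
                                n = 128L, ps = 0.212, amp = 300) {
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  rowg <- matrix(seq_len(n), n, n)
  colg <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((rowg - ctr[1])^2 + (colg - ctr[2])^2)
  Rpx <- radiusUm / ps
  filled <- rad <= Rpx
  ideal <- matrix(10, n, n)
  ideal[filled] <- 100
  for (a in angles) {
    dirv <- c(sin(a), cos(a))
    p0 <- ctr + Rpx * dirv
    p1 <- ctr + (Rpx + lengthUm / ps) * dirv
    vy <- p1[1] - p0[1]; vx <- p1[2] - p0[2]; l2 <- vy^2 + vx^2
    t <- pmin(pmax(((rowg - p0[1]) * vy + (colg - p0[2]) * vx) / l2, 0), 1)
    dseg <- sqrt((rowg - (p0[1] + t * vy))^2 + (colg - (p0[2] + t * vx))^2)
    sh <- dseg <= 0.6 & !filled
    ideal[sh] <- pmax(ideal[sh], 100)
    ideal <- ideal + amp * exp(-((rowg - p1[1])^2 + (colg - p1[2])^2) /
                                 (2 * 1.2^2)) * !filled
  }
  Micrograph(ideal, ps)
}

test_that("cells without filopodia yield no tips", {
  sc <- makeCellScene(SceneParams(seed = 41))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  expect_identical(nrow(radialTipSearch(img, cell)), 0L)
})

test_that("tips are recovered at truth positions and angles", {
  sc <- makeCellScene(SceneParams(nFilopodia = 4L, seed = 9))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  tips <- radialTipSearch(img, cell)
  tr <- sc$truth@cells[[1]]
  expect_identical(nrow(tips), 4L)
  for (i in seq_len(4)) {
    d <- sqrt((tips$tip_row - tr$tipRow[i])^2 +
              (tips$tip_col - tr$tipCol[i])^2) * img@pixelSizeUm
    j <- which.min(d)
    expect_lt(d[j], 0.5)
    adiff <- min(abs(tips$angle_rad[j] - tr$baseAngle[i]),
                 2 * pi - abs(tips$angle_rad[j] - tr$baseAngle[i]))
    expect_lt(adiff, 2 * pi / 180)
    # tips always lie outside the body mask
    expect_false(cell@bodyMask[round(tips$tip_row[j]), round(tips$tip_col[j])])
  }
})

test_that("the merge angle controls whether nearby filopodia collapse", {
  img <- drawnFilopodiaImage(c(0, 10 * pi / 180))
  cell <- segmentCells(img)[[1]]
  t5 <- radialTipSearch(img, cell, tipSearchConfig(mergeAngleDeg = 5))
  expect_identical(nrow(t5), 2L)
  t15 <- radialTipSearch(img, cell, tipSearchConfig(mergeAngleDeg = 15))
  expect_identical(nrow(t15), 1L)
})

test_that("raising the detection threshold never adds tips", {
  sc <- makeCellScene(SceneParams(nFilopodia = 3L, seed = 55))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  counts <- vapply(c(2, 4, 8, 30, 200), function(k)
    nrow(radialTipSearch(img, cell, tipSearchConfig(kSigma = k))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[[2]], 3L) # default k = 4 finds the truth
})

test_that("tips register to the nearest cell, with a deterministic tie rule", {
  pl <- lapply(c(2L, 3L, 4L), function(k)
    SceneParams(nFilopodia = k, seed = 200 + k))
  fd <- makeField(pl, fieldShape = c(440L, 440L), seed = 11, minGapUm = 8)
  img <- maxProject(fd$stack)
  cells <- segmentCells(img)
  expect_length(cells, 3L)
  allTips <- do.call(rbind, lapply(cells, function(cc)
    radialTipSearch(img, cc, allCells = cells)))
  reg <- registerTipsToCells(allTips, cells)
  # every registered tip sits within 0.5 um of a truth tip of the same cell
  for (i in seq_len(nrow(reg))) {
    cc <- cells[[which(vapply(cells, function(x)
      x@cellId == reg$cell_id[i], logical(1)))]]
    tr <- fd$truth@cells[[which.max(vapply(fd$truth@cells, function(tc)
      sum(tc$bodyMask & cc@bodyMask), numeric(1)))]]
    d <- sqrt((tr$tipRow - reg$tip_row[i])^2 +
              (tr$tipCol - reg$tip_col[i])^2) * 0.212
    expect_lt(min(d), 0.5)
  }
  expect_identical(nrow(reg), 9L)

  # constructed equidistant tip goes to the smaller cell id
  two <- matrix(10, 80, 128)
  rowg <- matrix(seq_len(80), 80, 128)
  colg <- matrix(seq_len(128), 80, 128, byrow = TRUE)
  two[(rowg - 40)^2 + (colg - 40)^2 <= 15^2] <- 100
  two[(rowg - 40)^2 + (colg - 88)^2 <= 15^2] <- 100
  img2 <- Micrograph(two, 0.212)
  cells2 <- segmentCells(img2)
  expect_length(cells2, 2L)
  tie <- data.frame(tip_row = 40, tip_col = 64, angle_rad = 0,
                    distance_um = 1, peak_intensity = 50, cell_id = NA)
  got <- registerTipsToCells(tie, cells2)
  expect_identical(got$cell_id, min(vapply(cells2, function(x) x@cellId,
                                           integer(1))))
})

test_that("distant tips are dropped during registration", {
  sc <- makeCellScene(SceneParams(seed = 60))
  cells <- segmentCells(maxProject(sc$stack))
  far <- data.frame(tip_row = 2, tip_col = 2, angle_rad = 0,
                    distance_um = 1, peak_intensity = 50, cell_id = NA)
  expect_message(got <- registerTipsToCells(far, cells, maxLengthUm = 2),
                 "dropped")
  expect_identical(nrow(got), 0L)
})

test_that("filopodia summaries follow the positive-cells-only convention", {
  s <- summarizeFilopodia(c(0, 0, 1, 3, 4))
  expect_equal(s$percentWithFilopodia, 60)
  expect_equal(s$meanCountPositive, 8 / 3)
  expect_equal(s$semCountPositive, stats::sd(c(1, 3, 4)) / sqrt(3))
  expect_identical(s$nPositive, 3L)
  z <- summarizeFilopodia(c(0, 0, 0), experiments = c("a", "a", "b"))
  expect_equal(z$percentWithFilopodia, 0)
  expect_equal(z$meanCountPositive, 0)
  expect_identical(z$nPositive, 0L)
  expect_identical(z$N, 2L)
})
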