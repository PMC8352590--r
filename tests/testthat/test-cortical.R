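test_that("ratio is exact on uniform cells and recovers enrichment", {
  sc <- makeCellScene(noiselessParams(enrichment = 1, seed = 3))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  expect_equal(cortexCytoRatio(img, partitionCortex(cell)), 1,
               tolerance = 0.01)
  for (E in c(1.0, 1.1, 1.2, 1.5, 1.8)) {
    sc <- makeCellScene(noiselessParams(enrichment = E, seed = 3))
    img <- maxProject(sc$stack)
    cell <- segmentCells(img)[[1]]
    part <- partitionCortex(cell)
    r <- cortexCytoRatio(img, part)
    expect_equal(r, E, tolerance = 0.02)
    # cross-check against brute-force pixel averaging on the truth masks
    tr <- sc$truth@cells[[1]]
    rb <- bruteForceRatio(pixels(img), tr$bandMask,
                          tr$filledMask & !tr$bandMask & !tr$nucleusMask)
    expect_equal(r, rb, tolerance = 0.02)
  }
})

test_that("ratio is invariant to gain; unmeasurable cells propagate flags", {
  sc <- makeCellScene(SceneParams(seed = 6))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  part <- partitionCortex(cell)
  r1 <- cortexCytoRatio(img, part)
  r2 <- cortexCytoRatio(Micrograph(pixels(img) * 3.7, img@pixelSizeUm), part)
  expect_equal(r1, r2, tolerance = 1e-12)
  thin <- matrix(FALSE, 40, 40); thin[18:22, 5:35] <- TRUE
  badPart <- partitionCortex(maskCellRecord(thin), 0.8)
  expect_warning(out <- cortexCytoRatio(img, badPart), "unmeasurable")
  expect_true(is.na(out))
})

test_that("cortical SD matches the cosine closed form and is zero when uniform", {
  # band = M (1 + A cos(theta - theta0)): SD across bins = M A / sqrt(2)
  sc <- makeCellScene(noiselessParams(enrichment = 1, polarityAmplitude = 0.5,
                                      polarityAngle = 1.1, seed = 5))
  img <- maxProject(sc$stack)
  cell <- truthCellRecord(sc$truth, 1, img)
  part <- truthPartition(sc$truth)
  res <- corticalAsymmetry(img, part, cell, nBins = 360L)
  expect_equal(res$corticalSd, 100 * 0.5 / sqrt(2), tolerance = 0.03)
  sc0 <- makeCellScene(noiselessParams(enrichment = 1.2, seed = 5))
  img0 <- maxProject(sc0$stack)
  res0 <- corticalAsymmetry(img0, truthPartition(sc0$truth),
                            truthCellRecord(sc0$truth, 1, img0))
  expect_lt(res0$corticalSd, 0.05 * 100 * 0.5 / sqrt(2))
})

test_that("polarized cells rank above uniform cells in asymmetry under noise", {
  wins <- 0L
  nrep <- 60L
  for (s in seq_len(nrep)) {
    scU <- makeCellScene(SceneParams(seed = 2000 + s))
    scP <- makeCellScene(SceneParams(polarityAmplitude = 0.5,
                                     seed = 3000 + s))
    sdOf <- function(sc) {
      img <- maxProject(sc$stack)
      corticalAsymmetry(img, truthPartition(sc$truth),
                        truthCellRecord(sc$truth, 1, img))$corticalSd
    }
    if (sdOf(scP) > sdOf(scU)) wins <- wins + 1L
  }
  expect_gte(wins / nrep, 0.95)
})

test_that("cortical SD scales with gain on raw intensities but not normalized", {
  sc <- makeCellScene(SceneParams(polarityAmplitude = 0.4, seed = 7))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  part <- partitionCortex(cell)
  img2 <- Micrograph(pixels(img) * 2.5, img@pixelSizeUm)
  raw1 <- corticalAsymmetry(img, part, cell)$corticalSd
  raw2 <- corticalAsymmetry(img2, part, cell)$corticalSd
  expect_equal(raw2, 2.5 * raw1, tolerance = 1e-10)
  nm1 <- corticalAsymmetry(img, part, cell, normalize = TRUE)$corticalSd
  nm2 <- corticalAsymmetry(img2, part, cell, normalize = TRUE)$corticalSd
  expect_equal(nm1, nm2, tolerance = 1e-10)
})

test_that("peripheral profile localizes the polarity angle and rotates with the image", {
  theta0 <- 0.8
  sc <- makeCellScene(noiselessParams(enrichment = 1.3,
                                      polarityAmplitude = 0.6,
                                      polarityAngle = theta0, seed = 8))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  prof <- peripheralProfile(img, partitionCortex(cell), cell, nBins = 360L)
  amax <- prof$angle_rad[which.max(prof$mean_intensity)]
  expect_lte(min(abs(amax - theta0), 2 * pi - abs(amax - theta0)),
             2 * 2 * pi / 360 + 1e-9)
  # uniform cell: flat profile
  scU <- makeCellScene(noiselessParams(enrichment = 1.3, seed = 8))
  imgU <- maxProject(scU$stack)
  cellU <- segmentCells(imgU)[[1]]
  profU <- peripheralProfile(imgU, partitionCortex(cellU), cellU)
  expect_lt(max(profU$mean_intensity, na.rm = TRUE) /
              min(profU$mean_intensity, na.rm = TRUE), 1.1)
  # rotating the image by 90 degrees shifts the profile by a quarter turn
  rot <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  imgR <- Micrograph(rot(pixels(img)), img@pixelSizeUm)
  cellR <- segmentCells(imgR)[[1]]
  profR <- peripheralProfile(imgR, partitionCortex(cellR), cellR,
                             nBins = 360L)
  amaxR <- profR$angle_rad[which.max(profR$mean_intensity)]
  expectedR <- atan2(-cos(theta0), sin(theta0)) # angle mapped by rotation
  expect_lte(min(abs(amaxR - expectedR), 2 * pi - abs(amaxR - expectedR)),
             3 * 2 * pi / 360 + 1e-9)
})

test_that("cellMetrics assembles ratio, SD and count in one row", {
  sc <- makeCellScene(SceneParams(nFilopodia = 2L, seed = 10))
  img <- maxProject(sc$stack)
  cell <- segmentCells(img)[[1]]
  m <- cellMetrics(img, cell)
  expect_identical(nrow(m), 1L)
  expect_identical(m$filopodia_count, 2L)
  expect_gt(m$cortex_cyto_ratio, 1)
  expect_gte(m$cortical_sd, 0)
})
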