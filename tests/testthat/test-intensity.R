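# Band means with corner exclusion, per-cell membrane profiles, myocardium
# summaries, outlier screening, min-max rfu.

mkImage <- function(mat, ps = 0.5, polylines = list(), cellId = "c1",
                    channels = "F-actin") {
  data <- array(mat, dim = c(nrow(mat), ncol(mat), length(channels)))
  new("CrossSectionImage", data = data, channels = channels, pixelSize = ps,
      axis = "X", polylines = polylines, cellId = cellId)
}

test_that("band mean equals a pixel-enumeration oracle", {
  # 20 x 20 image at 0.5 um/px; horizontal polyline through the middle,
  # interior below
  mat <- matrix(10, 20, 20)
  mat[, 11:20] <- 20  # left half 10, right half 20 (columns = x)
  pl <- cbind(c(2, 18), c(10, 10))  # pixel coords, horizontal at y = 5 um
  img <- mkImage(mat, ps = 0.5, polylines = list(basal = pl,
    apical = cbind(c(2, 18), c(2, 2)),
    "lateral-left" = cbind(c(2, 2), c(2, 10)),
    "lateral-right" = cbind(c(18, 18), c(2, 10))))
  bm <- bandMean(img, "basal", "F-actin", width = 1, cornerExclusion = 0)
  # oracle: enumerate the audited pixel set directly
  expect_equal(bm$mean, mean(mat[cbind(bm$pixels[, "row"], bm$pixels[, "col"])]))
  # the band spans both halves equally -> mean 15
  expect_equal(bm$mean, 15)
  # uniform image -> the constant, any band
  imgU <- mkImage(matrix(7, 20, 20), ps = 0.5, polylines = img@polylines)
  expect_equal(bandMean(imgU, "basal", "F-actin")$mean, 7)
})

test_that("corner exclusion removes corner contamination", {
  mat <- matrix(10, 20, 20)
  # corners of the basal membrane carry spill-over signal
  mat[9:10, 1:4] <- 99
  mat[9:10, 17:20] <- 99
  pl <- cbind(c(1, 19), c(10, 10))
  img <- mkImage(mat, ps = 0.5, polylines = list(basal = pl,
    apical = cbind(c(1, 19), c(2, 2)),
    "lateral-left" = cbind(c(1, 1), c(2, 10)),
    "lateral-right" = cbind(c(19, 19), c(2, 10))))
  noTrim <- bandMean(img, "basal", "F-actin", width = 1, cornerExclusion = 0)
  expect_gt(noTrim$mean, 10)
  trimmed <- bandMean(img, "basal", "F-actin", width = 1, cornerExclusion = 2)
  expect_equal(trimmed$mean, 10)
  expect_error(bandMean(img, "basal", "F-actin", cornerExclusion = 100),
               "trimming")
})

test_that("profiles reduce eight band means to percentages and basal ratio", {
  cfg <- smallQuietConfig()
  cell <- cuboidCell(12, 7, 5)
  # means basal = 6, lateral = 3, apical = 1 -> 60/30/10 and ratio 1.5
  tv <- uniformTruth(1)
  tv[["F-actin"]][] <- c(6, 1, 3, 3, 3, 3)
  tv[["pMyosin"]][] <- 2
  cell@membraneTruth <- tv
  imgX <- renderCrossSection(cell, "X", cfg)
  imgY <- renderCrossSection(cell, "Y", cfg)
  pr <- profileCell(imgX, imgY)
  fa <- pr[pr$channel == "F-actin", ]
  expect_equal(fa$pct_basal, 60, tolerance = 1e-9)
  expect_equal(fa$pct_lateral, 30, tolerance = 1e-9)
  expect_equal(fa$pct_apical, 10, tolerance = 1e-9)
  expect_equal(fa$basal_ratio, 1.5, tolerance = 1e-9)
  pm <- pr[pr$channel == "pMyosin", ]
  expect_equal(pm$pct_basal, 100 / 3, tolerance = 1e-9)
  expect_equal(pm$basal_ratio, 0.5, tolerance = 1e-9)
  expect_equal(fa$pct_basal + fa$pct_lateral + fa$pct_apical, 100,
               tolerance = 1e-6)
})

test_that("zero-noise generator round trip recovers fractions within 1%", {
  hd <- cachedFixture("smallHeart7", generateHeart(smallQuietConfig(seed = 7)))
  cfg <- hd$config
  cells <- Filter(function(c) trueRegion(c) == "OC", hd$cells)[1:6]
  for (cell in cells) {
    imgX <- renderCrossSection(cell, "X", cfg)
    imgY <- renderCrossSection(cell, "Y", cfg)
    pr <- profileCell(imgX, imgY)
    for (ch in c("F-actin", "pMyosin")) {
      f <- cfg@fractions$OC[[ch]]
      row <- pr[pr$channel == ch, ]
      got <- c(row$pct_basal, row$pct_lateral, row$pct_apical)
      expect_lt(max(abs(got - 100 * f)), 1)
    }
  }
})

test_that("basal ratio is invariant to global intensity rescaling", {
  cfg <- smallQuietConfig()
  cell <- cuboidCell(12, 7, 5)
  cell@membraneTruth <- uniformTruth(5)
  cell@membraneTruth[["F-actin"]][["basal"]] <- 12
  imgX <- renderCrossSection(cell, "X", cfg)
  imgY <- renderCrossSection(cell, "Y", cfg)
  r1 <- profileCell(imgX, imgY)
  gain <- 3.7
  imgX@data <- imgX@data * gain
  imgY@data <- imgY@data * gain
  r2 <- profileCell(imgX, imgY)
  expect_equal(r2$basal_ratio, r1$basal_ratio, tolerance = 1e-12)
  expect_equal(r2$pct_basal, r1$pct_basal, tolerance = 1e-12)
})

test_that("noisy cells recover the configured basal ratio within 5%", {
  cfg <- generatorConfig(cellCounts = c(OC = 26, IC = 10, neither = 12),
                         background = 0, seed = 21)
  cells <- c(generateCellPopulation(25, "OC", cfg, seed = 21),
             generateCellPopulation(25, "IC", cfg, seed = 22))
  for (r in c("OC", "IC")) {
    sub <- Filter(function(c) trueRegion(c) == r, cells)
    ratios <- vapply(seq_along(sub), function(i) {
      imgX <- renderCrossSection(sub[[i]], "X", cfg, seed = 500 + i)
      imgY <- renderCrossSection(sub[[i]], "Y", cfg, seed = 900 + i)
      pr <- profileCell(imgX, imgY)
      pr$basal_ratio[pr$channel == "F-actin"]
    }, numeric(1))
    f <- cfg@fractions[[r]][["F-actin"]]
    implied <- f[["basal"]] / (f[["apical"]] + f[["lateral"]])
    expect_lt(abs(mean(ratios) - implied) / implied, 0.05)
  }
})

test_that("myocardium means respect the mask", {
  img <- matrix(5, 30, 30)
  mask <- matrix(TRUE, 30, 30)
  expect_equal(myocardiumMean(img, mask), 5)
  img2 <- img; img2[, 16:30] <- 30; img2[, 1:15] <- 10
  expect_equal(myocardiumMean(img2, mask), 20)  # weighted-mean oracle
  # endocardial region of value 100 excluded by the mask
  img3 <- img; img3[10:20, 10:20] <- 100
  mask3 <- mask; mask3[10:20, 10:20] <- FALSE
  expect_equal(myocardiumMean(img3, mask3), 5)
  expect_error(myocardiumMean(img, mask & FALSE), "empty")
})

test_that("outlier screening applies Tukey fences", {
  expect_identical(screenOutliers(c(10, 11, 12, 11, 10)), rep(FALSE, 5))
  flags <- screenOutliers(c(10, 11, 12, 11, 100))
  expect_identical(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # quartile arithmetic oracle
  v <- c(10, 11, 12, 11, 100)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_identical(flags, v < q[1] - 1.5 * diff(q) | v > q[2] + 1.5 * diff(q))
  expect_identical(screenOutliers(rep(4, 6)), rep(FALSE, 6))  # IQR = 0
  expect_warning(screenOutliers(c(1, 2)), "fewer than 3")
})

test_that("min-max rfu spans [1, 10] and preserves structure", {
  expect_equal(minmaxRfu(c(5, 20)), c(1, 10))
  expect_equal(minmaxRfu(c(5, 10, 20)), c(1, 4, 10))
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(8)
    y <- minmaxRfu(x)
    expect_equal(min(y), 1)
    expect_equal(max(y), 10)
    expect_identical(order(y), order(x))
    # affine invariance
    expect_equal(minmaxRfu(3.2 * x + 7), y, tolerance = 1e-12)
  }
  expect_error(minmaxRfu(rep(2, 4)), "undefined")
  expect_error(minmaxRfu(3), "at least 2")
})

test_that("ventricle summaries flag outliers and rescale per replicate", {
  vals <- c(10, 12, 14, 13, 90, 20, 24, 28)
  reps <- c(rep("r1", 5), rep("r2", 3))
  emb <- paste0("e", 1:8)
  sv <- summarizeVentricles(vals, emb, reps)
  expect_true(sv$outlier_flag[5])
  expect_true(is.na(sv$rfu[5]))
  for (r in c("r1", "r2")) {
    keep <- sv$replicate_id == r & !sv$outlier_flag
    expect_equal(min(sv$rfu[keep]), 1)
    expect_equal(max(sv$rfu[keep]), 10)
  }
})
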