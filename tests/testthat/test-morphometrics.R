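# Shape metrics: apical tracing with stitching, circularity, cross-section
# widths and lateral lengths, apicobasal length, volume estimator.

test_that("planar outlines are traced in a single segment", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), 0)
  tr <- traceApical(sq)
  expect_equal(tr@area, 100)
  expect_equal(tr@perimeter, 40)
  expect_identical(tr@nSegments, 1L)
  tt <- seq(0, 2 * pi, length.out = 241)[-241]
  disc <- cbind(7 * cos(tt), 7 * sin(tt), 0)
  expect_equal(traceApical(disc)@area, pi * 49, tolerance = 0.005)
})

test_that("curved outlines are stitched and recover the surface area", {
  outline <- drapedOutline(R = 20, half = pi / 6, L = 12)
  trueArea <- 20 * (pi / 3) * 12  # cylindrical strip, dense integral
  tr <- traceApical(outline, curvatureThreshold = 1.0)
  expect_identical(tr@nSegments, 2L)
  expect_lt(abs(tr@area - trueArea) / trueArea, 0.02)
  # without stitching the single projection is visibly worse
  tr1 <- traceApical(outline, curvatureThreshold = Inf)
  expect_identical(tr1@nSegments, 1L)
  expect_gt(abs(tr1@area - trueArea) / trueArea,
            abs(tr@area - trueArea) / trueArea)
})

test_that("circularity follows the closed forms and the isoperimetric bound", {
  tt <- seq(0, 2 * pi, length.out = 301)[-301]
  circ <- cbind(5 * cos(tt), 5 * sin(tt), 0)
  expect_equal(computeCircularity(traceApical(circ)), 1, tolerance = 1e-3)
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2), 0)
  expect_equal(computeCircularity(traceApical(sq)), pi / 4, tolerance = 1e-12)
  rect <- cbind(c(0, 4, 4, 0), c(0, 0, 1, 1), 0)
  expect_equal(computeCircularity(traceApical(rect)), 16 * pi / 100,
               tolerance = 1e-12)
  expect_error(computeCircularity(10, 0), "perimeter")
  expect_error(computeCircularity(NaN, 4), "finite")
  # isoperimetric inequality on random star-shaped polygons
  set.seed(9)
  for (i in 1:50) {
    ang <- sort(runif(12, 0, 2 * pi))
    rad <- runif(12, 0.5, 3)
    poly <- cbind(rad * cos(ang), rad * sin(ang), 0)
    expect_lte(computeCircularity(traceApical(poly)), 1 + 1e-9)
  }
})

test_that("cross-sections of canonical prisms read the constructed widths", {
  cub <- cuboidCell(10, 6, 5)
  secs <- crossSectionMeasures(cub)
  # X section bisects the major (length-10) axis: widths read along y
  expect_equal(secs[[1]]$basalWidth, 6, tolerance = 1e-9)
  expect_equal(secs[[1]]$apicalWidth, 6, tolerance = 1e-9)
  expect_equal(secs[[2]]$basalWidth, 10, tolerance = 1e-9)
  expect_equal(sort(c(secs[[1]]$lateralLengths, secs[[2]]$lateralLengths)),
               rep(5, 4), tolerance = 1e-9)
  # truncated wedge: basal 12 x 12, apical 8 x 8, height 5
  ba <- cbind(c(0, 12, 12, 0), c(0, 0, 12, 12), 0)
  ap <- cbind(c(2, 10, 10, 2), c(2, 2, 10, 10), 5)
  wedge <- prismCell(ap, ba, heights = rep(5, 4), id = "wedge")
  ws <- suppressWarnings(crossSectionMeasures(wedge))  # square apical face
  for (s in ws) {
    expect_equal(s$basalWidth, 12, tolerance = 1e-9)
    expect_equal(s$apicalWidth, 8, tolerance = 1e-9)
    expect_equal(s$lateralLengths, rep(sqrt(2^2 + 5^2), 2), tolerance = 1e-9)
  }
  # prism with walls tilted 30 degrees from vertical, height 5
  sft <- 5 * tan(pi / 6)
  apT <- cbind(c(0, 10, 10, 0) + sft, c(0, 0, 6, 6), 5)
  baT <- cbind(c(0, 10, 10, 0), c(0, 0, 6, 6), 0)
  tilted <- prismCell(apT, baT, heights = rep(5, 4), id = "tilt")
  ts <- crossSectionMeasures(tilted)
  lats <- sort(c(ts[[1]]$lateralLengths, ts[[2]]$lateralLengths))
  expect_equal(lats, c(5, 5, 5 / cos(pi / 6), 5 / cos(pi / 6)),
               tolerance = 1e-6)
})

test_that("apicobasal length averages the four lateral membranes", {
  mkSecs <- function(lat) list(
    list(axis = "X", basalWidth = 1, apicalWidth = 1, lateralLengths = lat[1:2]),
    list(axis = "Y", basalWidth = 1, apicalWidth = 1, lateralLengths = lat[3:4]))
  expect_equal(apicobasalLength(mkSecs(c(5, 5, 5, 5))), 5)
  expect_equal(apicobasalLength(mkSecs(c(4, 5, 6, 5))), 5)
  set.seed(3)
  for (i in 1:20) {
    lat <- runif(4, 0.1, 20)
    expect_equal(apicobasalLength(mkSecs(lat)), sum(lat) / 4)  # brute sum
  }
  expect_error(apicobasalLength(mkSecs(c(1, 2, 3, 4))[1]), "two cross-sections")
})

test_that("volume estimator multiplies mean widths and length", {
  mkSecs <- function(bw, aw) list(
    list(axis = "X", basalWidth = bw[1], apicalWidth = aw[1],
         lateralLengths = c(1, 1)),
    list(axis = "Y", basalWidth = bw[2], apicalWidth = aw[2],
         lateralLengths = c(1, 1)))
  expect_equal(estimateVolume(mkSecs(c(10, 10), c(10, 10)), 5), 500)
  expect_equal(estimateVolume(mkSecs(c(12, 12), c(8, 8)), 5), 480)
  expect_equal(estimateVolume(mkSecs(c(12, 12), c(0, 0)), 5), 0)
  expect_error(estimateVolume(mkSecs(c(12, 12), c(8, 8)), -1), "length")
  # estimator bias on a square-frustum family: the width-product estimator
  # b*a*h undershoots the true frustum volume h/3*(b^2+ab+a^2) whenever the
  # faces differ (AM-GM: a^2+b^2 >= 2ab), with equality for the cuboid
  for (ratio in c(1, 0.8, 0.5, 0.2)) {
    b <- 10; a <- 10 * ratio; h <- 5
    est <- estimateVolume(mkSecs(c(b, b), c(a, a)), h)
    trueV <- h / 3 * (b^2 + b * a + a^2)  # frustum closed form
    expect_lte(est, trueV + 1e-9)
    if (ratio == 1) expect_equal(est, trueV) else expect_lt(est, trueV)
  }
})

test_that("metrics are scale covariant and circularity scale invariant", {
  hd <- cachedFixture("smallHeart7", generateHeart(smallQuietConfig(seed = 7)))
  cell <- hd$cells[[5]]
  k <- 2.3
  scaled <- cell
  scaled@apicalOutline <- cell@apicalOutline * k
  scaled@basalOutline <- cell@basalOutline * k
  scaled@wallHeights <- cell@wallHeights * k
  # the stitching threshold is a physical length, so it scales with the cell
  m1 <- measureCells(list(cell), curvatureThreshold = 1)
  m2 <- measureCells(list(scaled), curvatureThreshold = k)
  expect_equal(m2$apical_area, k^2 * m1$apical_area, tolerance = 1e-6)
  expect_equal(m2$apicobasal_length, k * m1$apicobasal_length, tolerance = 1e-6)
  expect_equal(m2$volume, k^3 * m1$volume, tolerance = 1e-6)
  expect_equal(m2$circularity, m1$circularity, tolerance = 1e-9)
})

test_that("zero-noise pipeline recovers generated apical areas within 2%", {
  hd <- cachedFixture("smallHeart7", generateHeart(smallQuietConfig(seed = 7)))
  m <- measureCells(hd$cells)
  truth <- vapply(hd$cells, function(c)
    cardiocurve:::projectedPolygonArea(apicalOutline(c)), numeric(1))
  expect_lt(max(abs(m$apical_area - truth) / truth), 0.02)
  expect_lt(abs(mean(m$apical_area) - mean(truth)) / mean(truth), 0.02)
})
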