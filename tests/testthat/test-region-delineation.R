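# Landmark placement, boundary construction, half-body assignment and
# mosaic cell selection.

test_that("48 hpf landmark arc fractions follow the closed forms", {
  # hand-arithmetic oracle: PB at 9, DB_OFT at 99 -> DB at 9 + (2/3)*90 = 69
  h <- heartModel("48", bendRadius = 60, tubeRadius = 30, bendAngle = 1.1)
  expect_equal(ocArc(h)$length, 99)
  lm <- locateLandmarks48(h, cellDiameter = 9)
  expect_equal(lm@pbOc, 9)
  expect_equal(lm@dbOc, 69, tolerance = 1e-9)
  lm0 <- locateLandmarks48(h, cellDiameter = 0)
  expect_equal(lm0@pbOc, 0)  # PB_OC coincides with the AVC
  # IC: PB at 0, DB_OFT at 80 -> DB at 40
  h2 <- heartModel("48", bendRadius = 94, tubeRadius = 30, bendAngle = 1.25)
  expect_equal(icArc(h2)$length, 80)
  lm2 <- locateLandmarks48(h2)
  expect_equal(lm2@dbIc, 40, tolerance = 1e-9)
})

test_that("landmark fraction identities hold to 1e-9 over random geometries", {
  set.seed(42)
  for (i in 1:100) {
    h <- randomHeartGeometry()
    lm <- if (stageOf(h) == "48") locateLandmarks48(h) else locateLandmarks36(h)
    expect_lt(abs(lm@dbOc - (lm@pbOc + (2 / 3) * (lm@dbOftOc - lm@pbOc))), 1e-9)
    expect_lt(abs(lm@dbIc - (lm@pbIc + 0.5 * (lm@dbOftIc - lm@pbIc))), 1e-9)
    if (stageOf(h) == "48") {
      pI <- cardiocurve:::arcPoint(lm@ocArc, (lm@pbOc + lm@dbOc) / 2)
      expect_lt(max(abs(lm@points$I - pI)), 1e-9)
      pII <- lm@arcPoints$pbIc + (lm@points$I - lm@arcPoints$pbIc) / 3
      expect_lt(max(abs(lm@points$II - pII)), 1e-9)
      pIII <- (lm@arcPoints$dbIc + lm@arcPoints$dbOc) / 2
      expect_lt(max(abs(lm@points$III - pIII)), 1e-9)
    } else {
      seg <- lm@arcPoints$pbIc - lm@arcPoints$pbOc
      expect_lt(max(abs(lm@points$I - (lm@arcPoints$pbOc + seg / 3))), 1e-9)
      expect_lt(max(abs(lm@points$II - (lm@arcPoints$pbOc + 2 * seg / 3))), 1e-9)
      segD <- lm@arcPoints$dbIc - lm@arcPoints$dbOc
      expect_lt(max(abs(lm@points$III - (lm@arcPoints$dbOc + segD / 3))), 1e-9)
      expect_lt(max(abs(lm@points$IV - (lm@arcPoints$dbOc + 2 * segD / 3))), 1e-9)
    }
  }
})

test_that("oversized cell diameter is rejected", {
  h <- heartModel("48")
  expect_error(locateLandmarks48(h, cellDiameter = ocArc(h)$length + 1),
               "cell diameter")
})

test_that("landmarks are equivariant under rigid motions of the heart", {
  h <- heartModel("48")
  lm <- locateLandmarks48(h)
  ang <- 0.7; tr <- c(31, -12)
  h2 <- transformHeart(h, ang, tr)
  lm2 <- locateLandmarks48(h2)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  moved <- function(p) as.numeric(R %*% p) + tr
  for (nm in names(lm@points))
    expect_equal(lm2@points[[nm]], moved(lm@points[[nm]]), tolerance = 1e-8)
  for (nm in names(lm@arcPoints))
    expect_equal(lm2@arcPoints[[nm]], moved(lm@arcPoints[[nm]]), tolerance = 1e-8)
  # arc positions are intrinsic and unchanged
  expect_equal(lm2@dbOc, lm@dbOc)
  expect_equal(lm2@dbIc, lm@dbIc)
})

test_that("region predicates classify canonical points correctly", {
  h <- heartModel("48")
  lm <- locateLandmarks48(h)
  b <- buildRegionBoundaries(lm)
  midOc <- cardiocurve:::arcPoint(b@ocArc, (lm@pbOc + lm@dbOc) / 2)
  expect_identical(regionOf(b, midOc), "OC")
  midIc <- cardiocurve:::arcPoint(b@icArc, (lm@pbIc + lm@dbIc) / 2)
  # nudge the IC arc point slightly towards the tissue interior (radially
  # outward from the bend centre) so it is strictly inside the polygon
  outward <- (midIc - h@origin) / sqrt(sum((midIc - h@origin)^2))
  expect_identical(regionOf(b, midIc + 0.5 * outward), "IC")
  distal <- cardiocurve:::arcPoint(b@icArc, lm@dbIc + 8)
  expect_identical(regionOf(b, distal + 0.5 * outward), "neither")
  if (requireNamespace("mgcv", quietly = TRUE)) {
    # independent point-in-polygon oracle on the IC polygon
    pts <- rbind(midIc + 0.5 * outward, distal + 0.5 * outward)
    oracle <- mgcv::in.out(rbind(b@icPolygon, b@icPolygon[1, ]), pts)
    expect_identical(as.vector(oracle), c(TRUE, FALSE))
  }
})

test_that("36 hpf boundaries leave the strip between medial borders unclaimed", {
  h <- heartModel("36")
  lm <- locateLandmarks36(h)
  b <- buildRegionBoundaries(lm)
  # midpoint between Points I and II lies between the medial borders
  mid <- (lm@points$I + lm@points$II) / 2
  expect_identical(regionOf(b, mid), "neither")
  # just outside the OC medial border on the OC side -> OC
  ocSide <- lm@points$I + 0.9 * (cardiocurve:::arcPoint(b@ocArc,
            (lm@pbOc + lm@dbOc) / 2) - lm@points$I)
  expect_identical(regionOf(b, ocSide), "OC")
})

test_that("half-body assignment matches an exact polygon-clip oracle", {
  hd <- defaultHeart()
  b <- hd$boundaries
  a <- b@ocCut$a; bb <- b@ocCut$b
  d <- (bb - a) / sqrt(sum((bb - a)^2))
  nrm <- c(-d[2], d[1])
  ref <- sign(sum((b@ocCut$sideRef - a) * nrm))
  nrm <- nrm * ref  # points to the convex (OC) side
  mid <- (a + bb) / 2
  mkRect <- function(frIn) {
    # rectangle straddling the cut with fraction frIn on the OC side,
    # drawn flat in the lateral plane at y = tubeRadius (off the surface,
    # geometry is irrelevant to the predicate)
    wIn <- 10 * frIn; wOut <- 10 * (1 - frIn)
    p1 <- mid - 4 * d - wOut * nrm; p2 <- mid + 4 * d - wOut * nrm
    p3 <- mid + 4 * d + wIn * nrm; p4 <- mid - 4 * d + wIn * nrm
    xy <- rbind(p1, p2, p3, p4)
    cbind(xy[, 1], 5, xy[, 2])
  }
  exactFraction <- function(rect3) {
    xy <- lateralProject(rect3)
    clipped <- cardiocurve:::clipPolygonHalfplane(xy, a, nrm)
    cardiocurve:::polygonArea(clipped) / cardiocurve:::polygonArea(xy)
  }
  rect40 <- mkRect(0.4); rect100 <- mkRect(1.0)
  expect_equal(exactFraction(rect40), 0.4, tolerance = 1e-9)
  lower <- function(m) t(t(m) - c(0, 2, 0))
  cells <- list(prismCell(rect40, lower(rect40), heights = rep(2, 4),
                          id = "straddle"),
                prismCell(rect100, lower(rect100), heights = rep(2, 4),
                          id = "inside"))
  asn <- assignCells(cells, b)
  expect_identical(asn$region[asn$cell_id == "straddle"], "neither")
  expect_identical(asn$region[asn$cell_id == "inside"], "OC")
  expect_equal(asn$in_region_area_fraction[asn$cell_id == "inside"], 1.0)
  expect_equal(asn$in_region_area_fraction[asn$cell_id == "straddle"], 0.4,
               tolerance = 0.05)
})

test_that("OC and IC assignments are disjoint and match generation truth", {
  hd <- defaultHeart()
  asn <- defaultAssignment()
  expect_identical(anyDuplicated(asn$cell_id), 0L)
  truth <- vapply(hd$cells, trueRegion, character(1))
  agree <- mean(asn$region == truth[match(asn$cell_id,
                                          vapply(hd$cells, cellId, character(1)))])
  expect_gte(agree, 0.95)
  # region only with at least half the body inside
  expect_true(all(asn$in_region_area_fraction[asn$region != "neither"] >= 0.5))
  # proximal/distal split only for OC cells
  expect_true(all(asn$subregion[asn$region != "OC"] == "n/a"))
  expect_true(all(asn$subregion[asn$region == "OC"] %in% c("proximal", "distal")))
})

test_that("assignments are invariant under rigid motions", {
  hd <- cachedFixture("smallHeart7", generateHeart(smallQuietConfig(seed = 7)))
  asn <- assignCells(hd$cells, hd$boundaries)
  ang <- -0.45; tr <- c(-18, 9)
  h2 <- transformHeart(hd$heart, ang, tr)
  b2 <- buildRegionBoundaries(locateLandmarks(h2))
  cells2 <- lapply(hd$cells, transformCell, angle = ang, translation = tr)
  asn2 <- assignCells(cells2, b2)
  expect_identical(asn$region, asn2$region)
  expect_identical(asn$subregion, asn2$subregion)
})

test_that("mosaic selection follows the two-step contact rule", {
  # chain: donor d1 - host h1 - host h2 - host h3, plus host far away
  mkCell <- function(id, clone, nbs) {
    c <- cuboidCell(6, 4, 3, id = id)
    c@cloneLabel <- clone
    c@neighbors <- nbs
    c
  }
  cells <- list(mkCell("d1", "donor", "h1"),
                mkCell("h1", "host", c("d1", "h2")),
                mkCell("h2", "host", c("h1", "h3")),
                mkCell("h3", "host", "h2"),
                mkCell("h4", "host", character(0)))
  asn <- data.frame(cell_id = c("d1", "h1", "h2", "h3", "h4"),
                    region = c("OC", "OC", "OC", "OC", "OC"),
                    stringsAsFactors = FALSE)
  sel <- selectMosaicCells(asn, cells)
  expect_identical(sel$donor, "d1")
  expect_setequal(sel$host, c("h1", "h2"))  # distance 1 and 2, not 3
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_edgelist(
      rbind(c("d1", "h1"), c("h1", "h2"), c("h2", "h3")), directed = FALSE)
    d <- igraph::distances(g, v = "d1")
    oracle <- colnames(d)[d[1, ] <= 2 & colnames(d) != "d1"]
    expect_setequal(sel$host, intersect(oracle, c("h1", "h2", "h3", "h4")))
  }
  # donor outside both regions is excluded
  asn2 <- asn; asn2$region[1] <- "neither"
  sel2 <- selectMosaicCells(asn2, cells)
  expect_identical(sel2$donor, character(0))
  # no donors at all -> both sets empty
  cells3 <- lapply(cells, function(c) { c@cloneLabel <- "host"; c })
  sel3 <- selectMosaicCells(asn, cells3)
  expect_identical(sel3$donor, character(0))
  expect_identical(sel3$host, character(0))
})
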