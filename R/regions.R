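# Region boundaries, point predicates, cell assignment, mosaic selection.

#' Build OC/IC region boundaries from landmarks
#'
#' At 48 hpf the OC is the surface on the convex side of the oblique-slicer
#' line through PB_OC and DB_OC (extruded perpendicular to the lateral-view
#' plane), and the IC is the lateral-view region enclosed by the segments
#' PB_IC -> Point II, Point II -> Point III, Point III -> DB_IC and the IC
#' arc between PB_IC and DB_IC. At 36-37 hpf both regions are polygons with
#' straight medial borders (OC: PB_OC -> I -> III -> DB_OC; IC: PB_IC -> II
#' -> IV -> DB_IC) and the strip between the two medial borders belongs to
#' neither region. Where the two predicates could both claim a point, the IC
#' takes precedence, keeping the regions mutually exclusive.
#'
#' @param landmarks an \linkS4class{ArcLandmarks}.
#' @return a \linkS4class{RegionBoundaries}.
#' @export
buildRegionBoundaries <- function(landmarks) {
  oc <- landmarks@ocArc; ic <- landmarks@icArc
  ocMidArc <- (landmarks@pbOc + landmarks@dbOc) / 2
  arcChunk <- function(arc, s0, s1, n = 120) {
    t(vapply(seq(s0, s1, length.out = n), function(s) arcPoint(arc, s),
             numeric(2)))
  }
  if (landmarks@stage == "48") {
    a <- landmarks@arcPoints$pbOc
    b <- landmarks@arcPoints$dbOc
    sideRef <- arcPoint(oc, ocMidArc)  # OC-arc midpoint: on the convex side
    backArc <- arcChunk(ic, landmarks@dbIc, landmarks@pbIc)
    icPoly <- rbind(landmarks@arcPoints$pbIc,
                    matrix(landmarks@points$II, 1),
                    matrix(landmarks@points$III, 1),
                    backArc[-nrow(backArc), , drop = FALSE])
    if (polygonSelfIntersects(icPoly)) stop("IC boundary polygon self-intersects")
    segs <- list(
      "OC cut" = rbind(a, b),
      "IC proximal border" = rbind(landmarks@arcPoints$pbIc, landmarks@points$II),
      "IC medial slicer" = rbind(landmarks@points$II, landmarks@points$III),
      "IC distal border" = rbind(landmarks@points$III, landmarks@arcPoints$dbIc))
    methods::new("RegionBoundaries", stage = "48", segments = segs,
                 ocCut = list(a = a, b = b, sideRef = sideRef),
                 ocPolygon = matrix(numeric(0), ncol = 2), icPolygon = icPoly,
                 ocMidArc = ocMidArc, ocArc = oc, icArc = ic)
  } else {
    ocPoly <- rbind(arcChunk(oc, landmarks@pbOc, landmarks@dbOc),
                    matrix(landmarks@points$III, 1),
                    matrix(landmarks@points$I, 1))
    icPoly <- rbind(arcChunk(ic, landmarks@pbIc, landmarks@dbIc),
                    matrix(landmarks@points$IV, 1),
                    matrix(landmarks@points$II, 1))
    if (polygonSelfIntersects(ocPoly)) stop("OC boundary polygon self-intersects")
    if (polygonSelfIntersects(icPoly)) stop("IC boundary polygon self-intersects")
    segs <- list(
      "OC medial border" = rbind(landmarks@points$I, landmarks@points$III),
      "IC medial border" = rbind(landmarks@points$II, landmarks@points$IV),
      "OC proximal border" = rbind(landmarks@arcPoints$pbOc, landmarks@points$I),
      "OC distal border" = rbind(landmarks@points$III, landmarks@arcPoints$dbOc),
      "IC proximal border" = rbind(landmarks@arcPoints$pbIc, landmarks@points$II),
      "IC distal border" = rbind(landmarks@points$IV, landmarks@arcPoints$dbIc))
    methods::new("RegionBoundaries", stage = landmarks@stage, segments = segs,
                 ocCut = list(), ocPolygon = ocPoly, icPolygon = icPoly,
                 ocMidArc = ocMidArc, ocArc = oc, icArc = ic)
  }
}

#' @describeIn buildRegionBoundaries classify lateral-view points as "OC",
#'   "IC" or "neither".
#' @param object a RegionBoundaries.
#' @param pts n x 2 matrix (or length-2 vector) of lateral-view points (um).
#' @export
setMethod("regionOf", "RegionBoundaries", function(object, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  res <- rep("neither", nrow(pts))
  inIc <- pointInPolygon(pts, object@icPolygon)
  res[inIc] <- "IC"
  if (object@stage == "48") {
    a <- object@ocCut$a; b <- object@ocCut$b
    nrm <- c(-(b[2] - a[2]), b[1] - a[1])
    ref <- sum((object@ocCut$sideRef - a) * nrm)
    d <- (pts[, 1] - a[1]) * nrm[1] + (pts[, 2] - a[2]) * nrm[2]
    res[!inIc & (d * ref >= 0)] <- "OC"
  } else {
    inOc <- pointInPolygon(pts, object@ocPolygon)
    res[!inIc & inOc] <- "OC"
  }
  res
})

#' Fraction of a cell's projected apical area inside a region
#'
#' Approximated on a deterministic grid of points spanning the projected
#' outline's bounding box, restricted to points inside the outline.
#'
#' @keywords internal
.regionFractions <- function(boundaries, outline2d, gridN = 28L) {
  bb <- apply(outline2d, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], length.out = gridN)
  gy <- seq(bb[1, 2], bb[2, 2], length.out = gridN)
  g <- cbind(rep(gx, times = gridN), rep(gy, each = gridN))
  inside <- pointInPolygon(g, outline2d)
  if (!any(inside)) stop("cell has zero projected area")
  reg <- regionOf(boundaries, g[inside, , drop = FALSE])
  c(OC = mean(reg == "OC"), IC = mean(reg == "IC"))
}

#' Assign cells to the OC or IC
#'
#' A cell belongs to a region when at least half of its body - operationalised
#' as the fraction of its lateral-view projected apical area - falls inside
#' that region's boundary. Cells with exactly half inside are assigned to the
#' region. OC cells are additionally split into proximal and distal groups at
#' the arc midpoint between PB_OC and DB_OC.
#'
#' @param cells list of \linkS4class{Cardiomyocyte} objects.
#' @param boundaries a \linkS4class{RegionBoundaries}.
#' @return data.frame with columns cell_id, embryo_id, region, subregion,
#'   in_region_area_fraction.
#' @export
assignCells <- function(cells, boundaries) {
  rows <- lapply(cells, function(cell) {
    proj <- lateralProject(cell@apicalOutline)
    if (polygonArea(proj) <= 0) stop(sprintf("cell %s has zero projected area", cell@cellId))
    fr <- .regionFractions(boundaries, proj)
    region <- "neither"; fraction <- 0
    if (fr[["IC"]] >= 0.5) { region <- "IC"; fraction <- fr[["IC"]] }
    else if (fr[["OC"]] >= 0.5) { region <- "OC"; fraction <- fr[["OC"]] }
    else fraction <- max(fr)
    sub <- "n/a"
    if (region == "OC") {
      ctr <- polygonCentroid(proj)
      sOc <- arcNearest(boundaries@ocArc, ctr)
      sub <- if (sOc < boundaries@ocMidArc) "proximal" else "distal"
    }
    data.frame(cell_id = cell@cellId, embryo_id = cell@embryoId,
               region = region, subregion = sub,
               in_region_area_fraction = unname(fraction),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select analysable donor and host cells in a mosaic heart
#'
#' Donor-derived cells qualify when assigned to the OC or IC. Host-derived
#' cells qualify when assigned to the OC or IC and lying within graph
#' distance 2 of a donor-derived cell on the cell-contact graph (direct
#' contact = 1, one cell-distance = 2).
#'
#' @param assignment data.frame from \code{\link{assignCells}}.
#' @param cells list of Cardiomyocyte objects carrying clone labels and the
#'   neighbour graph.
#' @return list(donor = character ids, host = character ids).
#' @export
selectMosaicCells <- function(assignment, cells) {
  ids <- vapply(cells, cellId, character(1))
  clone <- vapply(cells, function(c) c@cloneLabel, character(1))
  region <- assignment$region[match(ids, assignment$cell_id)]
  donorIdx <- which(clone == "donor")
  donorSet <- ids[donorIdx][region[donorIdx] != "neither"]
  if (length(donorIdx) == 0)
    return(list(donor = character(0), host = character(0)))
  # BFS from all donor cells to depth 2 on the neighbour graph
  adj <- lapply(cells, neighborIds)
  names(adj) <- ids
  dist <- stats::setNames(rep(Inf, length(ids)), ids)
  frontier <- ids[donorIdx]
  dist[frontier] <- 0
  for (depth in 1:2) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[nxt %in% ids]
    nxt <- nxt[!is.finite(dist[nxt])]
    dist[nxt] <- depth
    frontier <- nxt
    if (!length(frontier)) break
  }
  hostSet <- ids[clone == "host" & region != "neither" & is.finite(dist[ids])]
  list(donor = donorSet, host = hostSet)
}
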