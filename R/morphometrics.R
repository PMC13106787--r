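# Per-cell shape metrics: apical surface area (with stitching of curved
# cells), circularity, apicobasal length, and the L x W x H volume estimator.

#' Trace a cell's apical outline, stitching curved cells
#'
#' Emulates the en-face snapshot workflow: if the apical outline is nearly
#' planar (maximum out-of-plane deviation from its best-fit plane at most
#' \code{curvatureThreshold}), it is projected once onto that plane. A cell
#' that curves out of plane is split at the transverse plane of greatest
#' curvature (perpendicular to the outline's long axis), each side is
#' projected onto its own tangent plane, and the two projections are rejoined
#' along the cut so the stitched outline can be measured as one polygon.
#'
#' @param cell a \linkS4class{Cardiomyocyte}, or an n x 3 outline matrix.
#' @param curvatureThreshold out-of-plane deviation (um) above which the
#'   outline is split; default 1.0 um.
#' @param maxSegments maximum number of snapshot segments (default 2, i.e.
#'   at most one split).
#' @return an \linkS4class{ApicalTrace} with the stitched 2D outline, its
#'   area (um^2), perimeter (um) and the number of segments used.
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), 0)
#' traceApical(sq)@area  # 100
#' @export
traceApical <- function(cell, curvatureThreshold = 1.0, maxSegments = 2L) {
  outline <- if (methods::is(cell, "Cardiomyocyte")) cell@apicalOutline else cell
  if (!is.matrix(outline) || ncol(outline) != 3)
    stop("apical outline must be an n x 3 matrix")
  if (any(!is.finite(outline))) stop("apical outline contains non-finite values")
  pieces <- .splitUntilFlat(outline, curvatureThreshold, maxSegments)
  if (length(pieces$polys) == 1L) {
    xy <- .projectPiece(pieces$polys[[1]])
    out <- xy
  } else {
    out <- .stitchTwo(pieces$polys[[1]], pieces$polys[[2]], pieces$cut)
  }
  if (polygonSelfIntersects(out))
    stop(sprintf("stitched outline self-intersects (%d segments, %d vertices)",
                 length(pieces$polys), nrow(out)))
  a <- polygonArea(out)
  if (a <= 0) stop("traced outline has zero area")
  methods::new("ApicalTrace", outline2d = out,
               nSegments = length(pieces$polys),
               area = a, perimeter = polygonPerimeter(out))
}

.projectPiece <- function(poly3) projectToPlane(poly3, fitPlane(poly3))

# Split a 3D outline at the transverse plane of greatest curvature if its
# out-of-plane deviation exceeds the threshold. Returns list(polys, cut):
# cut holds the indices of the two inserted cut vertices within each piece.
.splitUntilFlat <- function(outline, threshold, maxSegments) {
  pl <- fitPlane(outline)
  if (max(abs(pl$deviations)) <= threshold || maxSegments < 2L)
    return(list(polys = list(outline), cut = NULL))
  longAxis <- svd(sweep(outline, 2, colMeans(outline)))$v[, 1]
  tcoord <- as.numeric(sweep(outline, 2, colMeans(outline)) %*% longAxis)
  # candidate transverse cuts: pick the one minimising the residual
  # out-of-plane deviation of the two halves (the plane of greatest
  # curvature is where splitting flattens the outline most)
  cand <- stats::quantile(tcoord, probs = seq(0.3, 0.7, by = 0.05), names = FALSE)
  best <- NULL; bestDev <- Inf
  for (tc in cand) {
    parts <- .cutPolygonAt(outline, tcoord, tc)
    if (is.null(parts)) next
    dev <- max(max(abs(fitPlane(parts$A)$deviations)),
               max(abs(fitPlane(parts$B)$deviations)))
    if (dev < bestDev) { bestDev <- dev; best <- parts }
  }
  if (is.null(best)) return(list(polys = list(outline), cut = NULL))
  list(polys = list(best$A, best$B), cut = best$cut)
}

# Cut a closed 3D polygon by the plane {t = tc} of the scalar field tcoord.
# Only the simple two-crossing case is handled; otherwise NULL.
.cutPolygonAt <- function(outline, tcoord, tc) {
  n <- nrow(outline)
  side <- tcoord >= tc
  if (all(side) || all(!side)) return(NULL)
  crossings <- which(side != side[c(2:n, 1L)])
  if (length(crossings) != 2L) return(NULL)
  interp <- function(i) {
    j <- if (i == n) 1L else i + 1L
    t <- (tc - tcoord[i]) / (tcoord[j] - tcoord[i])
    outline[i, ] + t * (outline[j, ] - outline[i, ])
  }
  c1 <- interp(crossings[1]); c2 <- interp(crossings[2])
  idx <- function(from, to) {  # vertex indices walking forward from..to
    if (from <= to) from:to else c(from:n, 1:to)
  }
  # piece A: vertices after crossing 1 up to crossing 2 (side flips there)
  iA <- idx((crossings[1] %% n) + 1L, crossings[2])
  iB <- idx((crossings[2] %% n) + 1L, crossings[1])
  A <- rbind(c1, outline[iA, , drop = FALSE], c2)
  B <- rbind(c2, outline[iB, , drop = FALSE], c1)
  if (nrow(A) < 3 || nrow(B) < 3) return(NULL)
  list(A = A, B = B, cut = list(A = c(1L, nrow(A)), B = c(1L, nrow(B))))
}

# Project both pieces to their own tangent planes and rejoin them along the
# cut segment: piece B is rigidly moved so its cut endpoints meet piece A's.
.stitchTwo <- function(A3, B3, cut) {
  A <- .projectPiece(A3); B <- .projectPiece(B3)
  aStart <- A[cut$A[1], ]; aEnd <- A[cut$A[2], ]
  bStart <- B[cut$B[2], ]; bEnd <- B[cut$B[1], ]  # B walks the cut reversed
  align <- function(P, from1, from2, to1, to2) {
    v1 <- from2 - from1; v2 <- to2 - to1
    ang <- atan2(v2[2], v2[1]) - atan2(v1[2], v1[1])
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    shifted <- sweep(P, 2, from1)
    sweep(shifted %*% t(R), 2, -to1)
  }
  Bal <- align(B, bStart, bEnd, aStart, aEnd)
  # reflect B across the cut if it would fold back onto A's side
  cutDir <- aEnd - aStart
  nrm <- c(-cutDir[2], cutDir[1])
  sideA <- sum((polygonCentroid(A) - aStart) * nrm)
  sideB <- sum((polygonCentroid(Bal) - aStart) * nrm)
  if (sideA * sideB > 0) {
    refl <- function(P, p0, d) {
      d <- d / sqrt(sum(d^2))
      Q <- sweep(P, 2, p0)
      comp <- Q %*% d
      sweep(2 * (comp %*% t(d)) - Q, 2, -p0)
    }
    Bal <- refl(Bal, aStart, cutDir)
  }
  # stitched boundary: A's non-cut path runs c1 -> ... -> c2 (indices 1..nA);
  # B's non-cut path continues c2 -> interior vertices -> c1, whose cut
  # endpoints after alignment coincide with A's, so drop the duplicates.
  nB <- nrow(Bal)
  pathA <- A[seq(cut$A[1], cut$A[2]), , drop = FALSE]
  pathB <- Bal[2:(nB - 1L), , drop = FALSE]
  rbind(pathA, pathB)
}

#' Circularity of a traced outline
#'
#' Defined as 4*pi*A / P^2: 1 for a circle, smaller for elongated shapes.
#'
#' @param trace an \linkS4class{ApicalTrace}, or a numeric area when
#'   \code{perimeter} is supplied.
#' @param perimeter optional perimeter when \code{trace} is a plain area.
#' @return dimensionless circularity.
#' @export
computeCircularity <- function(trace, perimeter = NULL) {
  if (methods::is(trace, "ApicalTrace")) {
    a <- trace@area; p <- trace@perimeter
  } else {
    a <- trace; p <- perimeter
  }
  if (!is.finite(a) || !is.finite(p) || p <= 0)
    stop("circularity needs finite area and positive perimeter")
  4 * pi * a / p^2
}

#' Cross-section measures along the apical outline's principal axes
#'
#' Places two cutting planes through the apical-outline centroid,
#' perpendicular to the apical surface: the X plane bisects the outline's
#' major axis and the Y plane its minor axis. Each plane intersects the
#' apical and basal outlines in two points; the section records the apical
#' width (distance between apical tips), basal width (between basal tips)
#' and the two lateral-membrane lengths (basal tip to apical tip, matched by
#' side).
#'
#' @param cell a \linkS4class{Cardiomyocyte}.
#' @return list of two data.frame-like lists with elements axis, basalWidth,
#'   apicalWidth, lateralLengths, and the tip coordinates (apicalTips,
#'   basalTips; 2 x 3 matrices).
#' @export
crossSectionMeasures <- function(cell) {
  ap <- cell@apicalOutline
  pl <- fitPlane(ap)
  xy <- projectToPlane(ap, pl)
  ctr2 <- colMeans(xy)
  mom <- stats::cov(xy)
  ev <- eigen(mom, symmetric = TRUE)
  if (ev$values[2] / ev$values[1] > 1 - 1e-6) {
    warning("apical outline is circularly symmetric; using fixed X/Y axes")
    # deterministic fallback: project the global x axis into the plane
    e1 <- as.numeric(crossprod(pl$basis, c(1, 0, 0)))
    if (sqrt(sum(e1^2)) < 1e-6)
      e1 <- as.numeric(crossprod(pl$basis, c(0, 1, 0)))
    e1 <- e1 / sqrt(sum(e1^2))
    axes2 <- cbind(e1, c(-e1[2], e1[1]))
  } else axes2 <- ev$vectors
  ctr3 <- pl$center + as.numeric(pl$basis %*% ctr2)
  major3 <- as.numeric(pl$basis %*% axes2[, 1])
  minor3 <- as.numeric(pl$basis %*% axes2[, 2])
  sections <- list(
    .sectionFromPlane(cell, ctr3, normal = major3, inPlane = minor3, axis = "X"),
    .sectionFromPlane(cell, ctr3, normal = minor3, inPlane = major3, axis = "Y"))
  sections
}

# Intersect the plane through `origin` with normal `normal` with the apical
# and basal outlines; pair tips by their sign along `inPlane`.
.sectionFromPlane <- function(cell, origin, normal, inPlane, axis) {
  tips <- function(poly) {
    d <- as.numeric(sweep(poly, 2, origin) %*% normal)
    n <- nrow(poly)
    pts <- matrix(numeric(0), ncol = 3)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if ((d[i] >= 0) != (d[j] >= 0)) {
        t <- d[i] / (d[i] - d[j])
        pts <- rbind(pts, poly[i, ] + t * (poly[j, ] - poly[i, ]))
      }
    }
    if (nrow(pts) < 2)
      stop("cutting plane misses the cell outline (degenerate section)")
    if (nrow(pts) > 2) {
      # keep the two extreme crossings along the in-plane direction
      u <- as.numeric(sweep(pts, 2, origin) %*% inPlane)
      pts <- pts[c(which.min(u), which.max(u)), , drop = FALSE]
    }
    u <- as.numeric(sweep(pts, 2, origin) %*% inPlane)
    pts[order(u), , drop = FALSE]
  }
  aTips <- tips(cell@apicalOutline)
  bTips <- tips(cell@basalOutline)
  apicalWidth <- sqrt(sum((aTips[1, ] - aTips[2, ])^2))
  basalWidth <- sqrt(sum((bTips[1, ] - bTips[2, ])^2))
  if (apicalWidth <= 0 && basalWidth <= 0)
    stop("degenerate (zero-width) cross-section")
  lat <- c(sqrt(sum((aTips[1, ] - bTips[1, ])^2)),
           sqrt(sum((aTips[2, ] - bTips[2, ])^2)))
  list(axis = axis, basalWidth = basalWidth, apicalWidth = apicalWidth,
       lateralLengths = lat, apicalTips = aTips, basalTips = bTips)
}

#' Apicobasal length from two cross-sections
#'
#' The arithmetic mean of the four lateral-membrane lengths (two per
#' section).
#'
#' @param sections list of two sections from \code{\link{crossSectionMeasures}}.
#' @return apicobasal length (um).
#' @export
apicobasalLength <- function(sections) {
  if (length(sections) != 2L)
    stop("apicobasal length needs exactly two cross-sections")
  lat <- c(sections[[1]]$lateralLengths, sections[[2]]$lateralLengths)
  if (length(lat) != 4L) stop("expected four lateral lengths")
  mean(lat)
}

#' Volume estimator: mean basal width x mean apical width x apicobasal length
#'
#' This is the reported field estimator, not a true geometric volume: for
#' non-cuboid cells it differs from the exact prism volume (it is an upper
#' bound for square-frustum shapes).
#'
#' @param sections list of two sections from \code{\link{crossSectionMeasures}}.
#' @param length apicobasal length (um).
#' @return volume estimate (um^3).
#' @export
estimateVolume <- function(sections, length) {
  if (length < 0) stop("length must be >= 0")
  bw <- c(sections[[1]]$basalWidth, sections[[2]]$basalWidth)
  aw <- c(sections[[1]]$apicalWidth, sections[[2]]$apicalWidth)
  if (any(bw < 0) || any(aw < 0)) stop("widths must be >= 0")
  mean(bw) * mean(aw) * length
}

#' Full morphometrics for a list of cells
#'
#' @param cells list of \linkS4class{Cardiomyocyte} objects.
#' @param assignment optional data.frame from \code{\link{assignCells}} used
#'   for region/subregion labels (falls back to ground-truth labels).
#' @param curvatureThreshold passed to \code{\link{traceApical}}.
#' @return data.frame with one row per cell: cell_id, embryo_id, region,
#'   subregion, genotype_label, clone_label, apical_area, circularity,
#'   apicobasal_length, volume.
#' @export
measureCells <- function(cells, assignment = NULL, curvatureThreshold = 1.0) {
  rows <- lapply(cells, function(cell) {
    tr <- traceApical(cell, curvatureThreshold)
    secs <- crossSectionMeasures(cell)
    len <- apicobasalLength(secs)
    vol <- estimateVolume(secs, len)
    region <- cell@trueRegion; sub <- "n/a"
    if (!is.null(assignment)) {
      i <- match(cell@cellId, assignment$cell_id)
      if (!is.na(i)) { region <- assignment$region[i]; sub <- assignment$subregion[i] }
    }
    data.frame(cell_id = cell@cellId, embryo_id = cell@embryoId,
               region = region, subregion = sub,
               genotype_label = cell@genotypeLabel,
               clone_label = cell@cloneLabel,
               apical_area = tr@area,
               circularity = computeCircularity(tr),
               apicobasal_length = len, volume = vol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
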