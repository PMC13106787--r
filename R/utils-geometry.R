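# Low-level planar/3D geometry helpers shared across modules.
# All coordinates are in micrometres unless a function says otherwise.

#' Signed area of a closed 2D polygon (shoelace)
#'
#' @param xy two-column matrix of vertices; the polygon is closed implicitly.
#' @return signed area; positive for counter-clockwise orientation.
#' @keywords internal
polygonSignedArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' @keywords internal
polygonArea <- function(xy) abs(polygonSignedArea(xy))

#' @keywords internal
polygonPerimeter <- function(xy) {
  d <- xy - xy[c(nrow(xy), seq_len(nrow(xy) - 1L)), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' @keywords internal
polygonCentroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  cx <- sum((xy[, 1] + xy[j, 1]) * cr) / (6 * a)
  cy <- sum((xy[, 2] + xy[j, 2]) * cr) / (6 * a)
  c(cx, cy)
}

#' Even-odd point-in-polygon test
#'
#' Vectorised over query points. Points exactly on an edge may fall on either
#' side; callers that care about boundary points should not rely on them.
#'
#' @param pts n x 2 matrix of query points.
#' @param poly m x 2 matrix of polygon vertices.
#' @return logical vector of length n.
#' @keywords internal
pointInPolygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  nv <- nrow(poly)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- (xj - xi) * (py[crosses] - yi) / (yj - yi) + xi
      flip <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
    j <- i
  }
  inside
}

#' Clip a polygon against a half-plane (Sutherland-Hodgman, one edge)
#'
#' Keeps the side where dot(p - a, normal) >= 0.
#' @keywords internal
clipPolygonHalfplane <- function(xy, a, normal) {
  n <- nrow(xy)
  d <- as.numeric((xy[, 1] - a[1]) * normal[1] + (xy[, 2] - a[2]) * normal[2])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi <- xy[i, ]; pj <- xy[j, ]
    if (d[i] >= 0) out <- rbind(out, pi)
    if ((d[i] >= 0) != (d[j] >= 0)) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, pi + t * (pj - pi))
    }
  }
  out
}

#' Does a closed polygon self-intersect?
#'
#' O(n^2) segment pair test, skipping adjacent edges.
#' @keywords internal
polygonSelfIntersects <- function(xy) {
  n <- nrow(xy)
  seg <- function(i) rbind(xy[i, ], xy[if (i == n) 1L else i + 1L, ])
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p1, p2, q1, q2) {
    d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
    d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 2L)) {
    s1 <- seg(i)
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      s2 <- seg(j)
      if (intersects(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Best-fit plane of a 3D point set
#'
#' Least-squares plane through the centroid via SVD. Returns the centroid,
#' an orthonormal in-plane basis (columns 1:2) and the unit normal.
#' @keywords internal
fitPlane <- function(pts) {
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  sv <- svd(centered)
  list(center = ctr, basis = sv$v[, 1:2, drop = FALSE], normal = sv$v[, 3],
       deviations = as.numeric(centered %*% sv$v[, 3]))
}

#' Project 3D points into a plane's 2D coordinates
#' @keywords internal
projectToPlane <- function(pts, plane) {
  sweep(pts, 2, plane$center) %*% plane$basis
}

#' Area of a 3D polygon projected onto its own best-fit plane
#' @keywords internal
projectedPolygonArea <- function(pts3) {
  polygonArea(projectToPlane(pts3, fitPlane(pts3)))
}

#' Evaluate a polyline arc at a given arc-length position
#'
#' @param arc list with `pts` (n x 2) and `s` (cumulative arc length).
#' @keywords internal
arcPoint <- function(arc, s) {
  if (length(s) != 1L || !is.finite(s)) stop("arc position must be a finite scalar")
  if (s < arc$s[1] - 1e-9 || s > arc$s[length(arc$s)] + 1e-9)
    stop(sprintf("arc position %.3f outside [%.3f, %.3f]",
                 s, arc$s[1], arc$s[length(arc$s)]))
  s <- min(max(s, arc$s[1]), arc$s[length(arc$s)])
  i <- findInterval(s, arc$s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(arc$s) - 1L)
  t <- (s - arc$s[i]) / (arc$s[i + 1] - arc$s[i])
  as.numeric(arc$pts[i, ] + t * (arc$pts[i + 1, ] - arc$pts[i, ]))
}

#' Arc-length position of the point on a polyline arc nearest to p
#' @keywords internal
arcNearest <- function(arc, p) {
  pts <- arc$pts
  n <- nrow(pts)
  a <- pts[-n, , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  ap1 <- p[1] - a[, 1]; ap2 <- p[2] - a[, 2]
  t <- pmin(pmax((ap1 * ab[, 1] + ap2 * ab[, 2]) / pmax(len2, 1e-300), 0), 1)
  qx <- a[, 1] + t * ab[, 1]; qy <- a[, 2] + t * ab[, 2]
  d2 <- (qx - p[1])^2 + (qy - p[2])^2
  i <- which.min(d2)
  arc$s[i] + t[i] * (arc$s[i + 1] - arc$s[i])
}

#' Build an arc list from a point matrix
#' @keywords internal
makeArc <- function(pts) {
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  list(pts = pts, s = c(0, cumsum(d)), length = sum(d))
}

#' Run code with a temporary RNG seed, restoring global RNG state afterwards
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a bounded child seed from a parent seed and a stream index
#' @keywords internal
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
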