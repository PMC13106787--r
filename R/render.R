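# Rendering of per-cell cross-section images.
#
# Each cell is bisected along the two principal axes of its apical outline,
# and each section is rasterised as a small multi-channel image: a membrane
# guide channel plus F-actin and pMyosin channels whose signal sits in a
# thin band just inside each membrane (basal, apical, two laterals), over a
# constant background, with optional Gaussian imaging noise.

.BAND_PX <- 3  # rendered band thickness, px inside the membrane contour

#' Render a cell cross-section image
#'
#' @param cell a \linkS4class{Cardiomyocyte} with positive wall heights.
#' @param axis "X" (plane bisecting the apical major axis) or "Y" (minor).
#' @param config a \linkS4class{GeneratorConfig} supplying pixel size,
#'   noise SD and background level.
#' @param seed optional seed for the noise draw; NULL uses the current RNG
#'   stream.
#' @return a \linkS4class{CrossSectionImage} with channels membrane,
#'   F-actin, pMyosin and ground-truth membrane polylines (pixel coords).
#' @export
renderCrossSection <- function(cell, axis = c("X", "Y"), config, seed = NULL) {
  axis <- match.arg(axis)
  if (any(cell@wallHeights <= 0)) stop("cell must have positive wall heights")
  secs <- crossSectionMeasures(cell)
  sec <- secs[[if (axis == "X") 1L else 2L]]
  if (sec$apicalWidth <= 1e-9 && sec$basalWidth <= 1e-9)
    stop("degenerate (zero-area) section")
  ps <- config@pixelSize
  # 2D frame in the cutting plane: ex along the apical width direction,
  # ey from basal towards apical
  aT <- sec$apicalTips; bT <- sec$basalTips
  ex <- aT[2, ] - aT[1, ]
  if (sqrt(sum(ex^2)) < 1e-9) ex <- bT[2, ] - bT[1, ]
  ex <- ex / sqrt(sum(ex^2))
  up <- (colMeans(aT) - colMeans(bT))
  ey <- up - sum(up * ex) * ex
  eyn <- sqrt(sum(ey^2))
  if (eyn < 1e-9) stop("degenerate (zero-area) section")
  ey <- ey / eyn
  orig <- colMeans(rbind(aT, bT))
  to2d <- function(p) c(sum((p - orig) * ex), sum((p - orig) * ey))
  b1 <- to2d(bT[1, ]); b2 <- to2d(bT[2, ])
  a1 <- to2d(aT[1, ]); a2 <- to2d(aT[2, ])
  quad <- rbind(b1, b2, a2, a1)
  if (polygonArea(quad) < 1e-9) stop("degenerate (zero-area) section")
  margin <- 2
  xmin <- min(quad[, 1]) - margin; xmax <- max(quad[, 1]) + margin
  ymin <- min(quad[, 2]) - margin; ymax <- max(quad[, 2]) + margin
  w <- ceiling((xmax - xmin) / ps); h <- ceiling((ymax - ymin) / ps)
  px <- (seq_len(w) - 0.5) * ps + xmin
  py <- (seq_len(h) - 0.5) * ps + ymin
  gx <- matrix(px, h, w, byrow = TRUE)
  gy <- matrix(py, h, w)
  # membrane segments with domain labels; laterals by section axis
  latNames <- if (axis == "X") c("lateral1", "lateral2") else c("lateral3", "lateral4")
  segs <- list(basal = rbind(b1, b2), apical = rbind(a1, a2),
               "lateral-left" = rbind(b1, a1), "lateral-right" = rbind(b2, a2))
  segDomain <- c("basal", "apical", latNames)
  dists <- lapply(segs, function(s) .segDist(gx, gy, s[1, ], s[2, ]))
  dstack <- vapply(dists, as.vector, numeric(h * w))
  nearestV <- max.col(-dstack, ties.method = "first")
  nearest <- matrix(nearestV, h, w)
  dmin <- matrix(dstack[cbind(seq_len(h * w), nearestV)], h, w)
  inQuad <- matrix(pointInPolygon(cbind(as.vector(gx), as.vector(gy)), quad), h, w)
  inBand <- inQuad & (dmin <= .BAND_PX * ps)
  channels <- c("membrane", names(cell@membraneTruth))
  peak <- max(1, unlist(cell@membraneTruth))
  bg <- config@background * peak
  data <- array(0, dim = c(h, w, length(channels)))
  data[, , 1] <- ifelse(dmin <= 1.0 * ps, peak, 0)
  noise <- function() {
    if (config@noiseSD == 0) 0 else
      matrix(stats::rnorm(h * w, 0, config@noiseSD), h, w)
  }
  draw <- function() {
    for (ci in seq_along(cell@membraneTruth)) {
      ch <- names(cell@membraneTruth)[ci]
      truth <- cell@membraneTruth[[ch]]
      vals <- matrix(0, h, w)
      for (si in 1:4) {
        pick <- inBand & (nearest == si)
        vals[pick] <- truth[[segDomain[si]]]
      }
      data[, , ci + 1L] <<- pmax(0, vals + bg + noise())
    }
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
  toPix <- function(s) cbind((s[, 1] - xmin) / ps, (s[, 2] - ymin) / ps)
  methods::new("CrossSectionImage", data = data, channels = channels,
               pixelSize = ps, axis = axis,
               polylines = lapply(segs, toPix), cellId = cell@cellId)
}

# distance from grid points to a 2D segment
.segDist <- function(gx, gy, p1, p2) {
  d <- p2 - p1
  len2 <- sum(d^2)
  t <- ((gx - p1[1]) * d[1] + (gy - p1[2]) * d[2]) / max(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  sqrt((gx - (p1[1] + t * d[1]))^2 + (gy - (p1[2] + t * d[2]))^2)
}
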