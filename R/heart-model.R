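# HeartModel construction and geometry queries.

#' Construct a parametric heart model
#'
#' The ventricle is modelled as a planar-bent tube: a circle of radius
#' \code{tubeRadius} swept along a circular arc of radius \code{bendRadius}
#' over \code{bendAngle} radians. Viewed in the bend (lateral-view) plane the
#' convex face is the outer curvature (OC) and the concave face the inner
#' curvature (IC). The proximal sector boundary is the AVC plane (arc
#' position 0 on both face arcs) and the distal boundary is the distal OFT
#' boundary (DB_OFT) on each face.
#'
#' @param stage developmental stage label: "36", "37" or "48".
#' @param bendRadius,tubeRadius,bendAngle geometry (um, um, rad). Defaults
#'   give a ventricle roughly 180 um along its long axis and 130 um across,
#'   sized so that typical regional cell counts tile comfortably.
#' @param cellDiameterTypical typical cell diameter (um) used as the
#'   "one cell diameter" landmark offset.
#' @param origin,phase rigid position of the bend centre in the lateral-view
#'   plane and rotation of the sector (rad); defaults place the AVC plane at
#'   angle 0 around the origin.
#' @return a \linkS4class{HeartModel}.
#' @examples
#' h <- heartModel("48")
#' ocArc(h)$length
#' @export
heartModel <- function(stage = "48", bendRadius = 130, tubeRadius = 65,
                       bendAngle = 1.4, cellDiameterTypical = 10,
                       origin = c(0, 0), phase = 0) {
  methods::new("HeartModel", stage = as.character(stage),
               bendRadius = bendRadius, tubeRadius = tubeRadius,
               bendAngle = bendAngle, origin = origin, phase = phase,
               cellDiameterTypical = cellDiameterTypical)
}

#' Evaluate the mid-surface (or an offset surface) at (s, theta)
#'
#' @param heart a HeartModel.
#' @param s arc length (um) along the mid-line from the AVC plane; vectorised.
#' @param theta circumferential angle (rad), 0 on the OC face; vectorised.
#' @param radialOffset offset (um) subtracted from the tube radius; positive
#'   values move towards the basal (inner) surface.
#' @return n x 3 matrix of 3D points (lateral-view plane is columns 1 and 3).
#' @export
midsurfacePoint <- function(heart, s, theta, radialOffset = 0) {
  phi <- heart@phase + s / heart@bendRadius
  rt <- heart@tubeRadius - radialOffset
  r <- heart@bendRadius + rt * cos(theta)
  cbind(heart@origin[1] + r * cos(phi),
        rt * sin(theta),
        heart@origin[2] + r * sin(phi))
}

#' Project 3D points to the lateral-view plane
#' @param pts n x 3 matrix.
#' @return n x 2 matrix (x, z).
#' @export
lateralProject <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  pts[, c(1, 3), drop = FALSE]
}

.faceArc <- function(heart, theta, n = 600) {
  r <- heart@bendRadius + heart@tubeRadius * cos(theta)
  phi <- heart@phase + seq(0, heart@bendAngle, length.out = n)
  pts <- cbind(heart@origin[1] + r * cos(phi),
               heart@origin[2] + r * sin(phi))
  # arc length is analytic (circular arc); the polyline only interpolates
  list(pts = pts, s = r * (phi - heart@phase), length = r * heart@bendAngle)
}

#' @describeIn heartModel OC-face arc (convex side) in the lateral-view
#'   plane, arc-length parameterised from the AVC plane.
#' @param object a HeartModel.
#' @export
setMethod("ocArc", "HeartModel", function(object, ...) .faceArc(object, 0))

#' @describeIn heartModel IC-face arc (concave side).
#' @export
setMethod("icArc", "HeartModel", function(object, ...) .faceArc(object, pi))

#' Distal OFT boundary arc positions
#'
#' @param heart a HeartModel.
#' @return named numeric: dbOftOc and dbOftIc (um along the respective arcs).
#' @export
oftBoundaries <- function(heart) {
  c(dbOftOc = (heart@bendRadius + heart@tubeRadius) * heart@bendAngle,
    dbOftIc = (heart@bendRadius - heart@tubeRadius) * heart@bendAngle)
}

#' Apply a rigid motion (lateral-view rotation + translation) to a heart
#'
#' Used to express that delineation is equivariant under specimen mounting:
#' rotating or translating the heart moves all landmarks with it and leaves
#' region assignments unchanged.
#'
#' @param heart a HeartModel.
#' @param angle rotation (rad) about the coordinate origin of the lateral
#'   plane.
#' @param translation length-2 lateral-plane translation (um).
#' @return the transformed HeartModel.
#' @export
transformHeart <- function(heart, angle = 0, translation = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  newOrigin <- as.numeric(R %*% heart@origin) + translation
  methods::initialize(heart, origin = newOrigin, phase = heart@phase + angle)
}

#' Apply the same rigid motion to a cardiomyocyte's geometry
#'
#' @param cell a Cardiomyocyte.
#' @param angle,translation as in \code{\link{transformHeart}}.
#' @return the transformed Cardiomyocyte.
#' @export
transformCell <- function(cell, angle = 0, translation = c(0, 0)) {
  R3 <- matrix(c(cos(angle), 0, sin(angle),
                 0, 1, 0,
                 -sin(angle), 0, cos(angle)), 3, 3)
  tr <- c(translation[1], 0, translation[2])
  move <- function(m) sweep(m %*% t(R3), 2, -tr)
  methods::initialize(cell,
                      apicalOutline = move(cell@apicalOutline),
                      basalOutline = move(cell@basalOutline))
}
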