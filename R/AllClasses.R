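# Central S4 classes. The heart is modelled as a planar-bent tube (a torus
# sector swept by a circle): the simplest surface with a distinct convex
# (outer-curvature, OC) and concave (inner-curvature, IC) face when the organ
# is viewed laterally, as dissected hearts are mounted for imaging.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' HeartModel: parametric mid-surface of a ventricle
#'
#' The mid-surface maps (s, theta) to 3D points, where s is arc length (um)
#' along the ventricular long axis measured on the mid-line from the
#' atrioventricular canal (AVC) plane, and theta is the circumferential angle
#' around the tube (theta = 0 on the OC face, pi on the IC face). The
#' lateral-view plane is the bend plane (x-z); y points out of the coverslip.
#'
#' @slot stage developmental stage label ("36", "37" or "48" hpf).
#' @slot bendRadius radius (um) of the bend mid-line.
#' @slot tubeRadius radius (um) of the swept tube circle.
#' @slot bendAngle angular extent (rad) of the sector; the AVC plane sits at
#'   angle 0 and the distal outflow-tract (OFT) boundary at \code{bendAngle}.
#' @slot origin 2D position (um) of the bend centre in the lateral-view plane.
#' @slot phase rotation (rad) of the sector within the lateral-view plane;
#'   together with \code{origin} this expresses rigid motions of the specimen.
#' @slot cellDiameterTypical typical cardiomyocyte diameter (um), used for the
#'   "one cell diameter from the AVC" landmark offset.
#' @export
setClass("HeartModel",
  representation(stage = "character", bendRadius = "numeric",
                 tubeRadius = "numeric", bendAngle = "numeric",
                 origin = "numeric", phase = "numeric",
                 cellDiameterTypical = "numeric"),
  prototype(stage = "48", origin = c(0, 0), phase = 0,
            cellDiameterTypical = 10))

setValidity("HeartModel", function(object) {
  msg <- character(0)
  if (!object@stage %in% c("36", "37", "48"))
    msg <- c(msg, "stage must be one of '36', '37', '48'")
  if (object@bendRadius <= 0 || object@tubeRadius <= 0)
    msg <- c(msg, "bendRadius and tubeRadius must be positive")
  if (object@tubeRadius >= object@bendRadius)
    msg <- c(msg, "tubeRadius must be smaller than bendRadius (inner arc must exist)")
  if (object@bendAngle <= 0 || object@bendAngle >= 2 * pi)
    msg <- c(msg, "bendAngle must be in (0, 2*pi)")
  if (length(object@origin) != 2) msg <- c(msg, "origin must be length-2")
  if (length(msg)) msg else TRUE
})

#' Cardiomyocyte: a labelled prism cell on the heart surface
#'
#' @slot cellId,embryoId identifiers.
#' @slot trueRegion generation ground truth: "OC", "IC" or "neither".
#' @slot center cell centre in (s, theta) surface coordinates.
#' @slot apicalOutline closed 3D polygon (n x 3, um) on the outer surface.
#' @slot basalOutline closed 3D polygon on the inner (basal) surface.
#' @slot wallHeights four lateral-wall lengths (um) at the principal-axis
#'   cross-section points.
#' @slot orientation list(axis = "circumferential"|"longitudinal", angle =
#'   radians of the apical-outline major axis relative to the circumferential
#'   direction).
#' @slot cloneLabel "host" or "donor" (mosaic analyses).
#' @slot genotypeLabel free-text genotype ("WT", "tbx5a", ...).
#' @slot membraneTruth per-channel list; each element a named numeric with
#'   entries basal, apical, lateral1, lateral2, lateral3, lateral4 (true mean
#'   intensities, arbitrary units).
#' @slot neighbors character vector of edge-sharing cell ids.
#' @export
setClass("Cardiomyocyte",
  representation(cellId = "character", embryoId = "character",
                 trueRegion = "character", center = "numeric",
                 apicalOutline = "matrix", basalOutline = "matrix",
                 wallHeights = "numeric", orientation = "list",
                 cloneLabel = "character", genotypeLabel = "character",
                 membraneTruth = "list", neighbors = "character"),
  prototype(trueRegion = "neither", cloneLabel = "host",
            genotypeLabel = "WT", neighbors = character(0),
            membraneTruth = list()))

setValidity("Cardiomyocyte", function(object) {
  msg <- character(0)
  if (!object@trueRegion %in% c("OC", "IC", "neither"))
    msg <- c(msg, "trueRegion must be 'OC', 'IC' or 'neither'")
  if (ncol(object@apicalOutline) != 3 || nrow(object@apicalOutline) < 3)
    msg <- c(msg, "apicalOutline must be an n x 3 matrix with n >= 3")
  if (length(object@wallHeights) != 4 || any(object@wallHeights <= 0))
    msg <- c(msg, "wallHeights must be four positive lengths")
  for (ch in names(object@membraneTruth)) {
    v <- object@membraneTruth[[ch]]
    if (any(v < 0)) msg <- c(msg, sprintf("membraneTruth[%s] has negative values", ch))
  }
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: study conditions for the synthetic-ventricle generator
#'
#' Per-region parameters are named numeric vectors with entries OC, IC and
#' neither. The wild-type 48 hpf OC apical-area parameters (mean 142 um^2,
#' SD 43 um^2) and the OC cell count follow the reported reference
#' distribution; every other default is a free modelling choice documented in
#' the methods vignette.
#'
#' @slot stage stage label.
#' @slot cellCounts cells per region.
#' @slot areaMean,areaSD per-region apical-area distribution (um^2).
#' @slot elongMean,elongSD per-region major/minor elongation ratio.
#' @slot heightMean,heightSD per-region apicobasal length (um).
#' @slot fractions list per region of per-channel (basal, lateral, apical)
#'   intensity fraction triplets, each summing to 1.
#' @slot intensityScale mean total intensity level per cell (arbitrary units).
#' @slot noiseSD Gaussian imaging noise SD (intensity units).
#' @slot background background level as a fraction of the peak truth value.
#' @slot pixelSize um per pixel for rendered cross-sections (default 0.3,
#'   matching the acquisition slice thickness).
#' @slot bendRadius,tubeRadius,bendAngle heart geometry (um, um, rad).
#' @slot cellDiameterTypical um.
#' @slot donorFraction fraction of cells labelled as donor-derived clones.
#' @slot genotype genotype label stamped on all generated cells.
#' @slot embryoId embryo identifier.
#' @slot seed integer RNG seed.
#' @export
setClass("GeneratorConfig",
  representation(stage = "character", cellCounts = "numeric",
                 areaMean = "numeric", areaSD = "numeric",
                 elongMean = "numeric", elongSD = "numeric",
                 heightMean = "numeric", heightSD = "numeric",
                 fractions = "list", intensityScale = "numeric",
                 noiseSD = "numeric", background = "numeric",
                 pixelSize = "numeric", bendRadius = "numeric",
                 tubeRadius = "numeric", bendAngle = "numeric",
                 cellDiameterTypical = "numeric", donorFraction = "numeric",
                 genotype = "character", embryoId = "character",
                 seed = "numeric"))

setValidity("GeneratorConfig", function(object) {
  msg <- character(0)
  reg <- c("OC", "IC", "neither")
  for (nm in c("cellCounts", "areaMean", "areaSD", "elongMean", "elongSD",
               "heightMean", "heightSD")) {
    v <- slot(object, nm)
    if (!all(reg %in% names(v)))
      msg <- c(msg, sprintf("%s must be named with OC, IC, neither", nm))
  }
  if (any(object@cellCounts <= 0)) msg <- c(msg, "cell counts must be > 0")
  if (any(object@areaSD < 0) || any(object@heightSD < 0))
    msg <- c(msg, "SDs must be >= 0")
  for (r in names(object@fractions)) {
    for (ch in names(object@fractions[[r]])) {
      f <- object@fractions[[r]][[ch]]
      if (length(f) != 3 || abs(sum(f) - 1) > 1e-9)
        msg <- c(msg, sprintf("fraction triplet %s/%s must sum to 1", r, ch))
      if (any(f < 0)) msg <- c(msg, sprintf("fraction triplet %s/%s negative", r, ch))
    }
  }
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ArcLandmarks: named landmark positions bounding the OC and IC
#'
#' Arc positions are micrometre arc lengths along the OC-side or IC-side
#' surface curve in the lateral-view plane. The named Points I-IV are 2D
#' lateral-view coordinates; which points exist depends on the stage.
#'
#' @slot stage stage label.
#' @slot pbOc,dbOc,dbOftOc arc positions on the OC arc.
#' @slot pbIc,dbIc,dbOftIc arc positions on the IC arc.
#' @slot points named list of 2D points ("I", "II", "III", optionally "IV").
#' @slot arcPoints named list of the 2D coordinates of the arc landmarks.
#' @slot ocArc,icArc the arc polylines (lists with pts, s, length) the
#'   landmarks refer to.
#' @export
setClass("ArcLandmarks",
  representation(stage = "character", pbOc = "numeric", dbOc = "numeric",
                 dbOftOc = "numeric", pbIc = "numeric", dbIc = "numeric",
                 dbOftIc = "numeric", points = "list", arcPoints = "list",
                 ocArc = "list", icArc = "list"))

setValidity("ArcLandmarks", function(object) {
  msg <- character(0)
  if (!(object@pbOc >= 0 && object@pbOc < object@dbOc &&
        object@dbOc <= object@dbOftOc + 1e-9))
    msg <- c(msg, "need 0 <= PB_OC < DB_OC <= DB_OFT(OC)")
  if (!(object@pbIc >= 0 && object@pbIc < object@dbIc &&
        object@dbIc <= object@dbOftIc + 1e-9))
    msg <- c(msg, "need 0 <= PB_IC < DB_IC <= DB_OFT(IC)")
  if (object@stage == "48") {
    if (abs(object@dbOc - (object@pbOc + (2 / 3) * (object@dbOftOc - object@pbOc))) > 1e-9)
      msg <- c(msg, "at 48 hpf DB_OC must lie at 2/3 of PB_OC -> DB_OFT(OC)")
    if (abs(object@dbIc - (object@pbIc + 0.5 * (object@dbOftIc - object@pbIc))) > 1e-9)
      msg <- c(msg, "at 48 hpf DB_IC must lie at 1/2 of PB_IC -> DB_OFT(IC)")
  }
  if (length(msg)) msg else TRUE
})

#' RegionBoundaries: lateral-view boundary segments and region predicates
#'
#' @slot stage stage label.
#' @slot segments named list of 2 x 2 matrices (point pairs) with role names
#'   such as "OC cut", "IC proximal border".
#' @slot ocCut for 48 hpf: list(a, b, sideRef) defining the oblique-slicer
#'   line through PB_OC and DB_OC and a reference point on the convex side.
#' @slot ocPolygon,icPolygon closed lateral-view polygons (36 hpf uses both;
#'   48 hpf uses icPolygon plus the ocCut half-plane).
#' @slot ocMidArc arc position splitting the proximal and distal OC.
#' @slot ocArc,icArc the arcs used to build the boundaries.
#' @export
setClass("RegionBoundaries",
  representation(stage = "character", segments = "list", ocCut = "list",
                 ocPolygon = "matrix", icPolygon = "matrix",
                 ocMidArc = "numeric", ocArc = "list", icArc = "list"))

#' CrossSectionImage: a rendered (or imported) cell cross-section
#'
#' @slot data h x w x channel array of non-negative intensities.
#' @slot channels channel names (membrane, F-actin, pMyosin).
#' @slot pixelSize um per pixel.
#' @slot axis "X" (plane bisecting the major axis) or "Y" (minor axis).
#' @slot polylines named list of 2-column matrices in pixel coordinates with
#'   names basal, apical, lateral-left, lateral-right: the ground-truth (or
#'   user-traced) membrane polylines.
#' @slot cellId id of the sectioned cell.
#' @export
setClass("CrossSectionImage",
  representation(data = "array", channels = "character", pixelSize = "numeric",
                 axis = "character", polylines = "list", cellId = "character"))

setValidity("CrossSectionImage", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3) msg <- c(msg, "data must be h x w x channels")
  if (min(object@data) < 0) msg <- c(msg, "intensities must be >= 0")
  if (dim(object@data)[3] != length(object@channels))
    msg <- c(msg, "channel count must match channel names")
  if (!object@axis %in% c("X", "Y")) msg <- c(msg, "axis must be 'X' or 'Y'")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  h <- dim(object@data)[1]; w <- dim(object@data)[2]
  for (nm in names(object@polylines)) {
    pl <- object@polylines[[nm]]
    if (any(pl[, 1] < 0 | pl[, 1] > w | pl[, 2] < 0 | pl[, 2] > h))
      msg <- c(msg, sprintf("polyline '%s' outside image bounds", nm))
  }
  if (length(msg)) msg else TRUE
})

#' ApicalTrace: stitched en-face outline of a cell's apical surface
#'
#' @slot outline2d closed 2D polygon (um) after tangent-plane unfolding.
#' @slot nSegments number of snapshot segments stitched together.
#' @slot area,perimeter um^2 and um, measured on the stitched polygon.
#' @export
setClass("ApicalTrace",
  representation(outline2d = "matrix", nSegments = "integer",
                 area = "numeric", perimeter = "numeric"))

setValidity("ApicalTrace", function(object) {
  msg <- character(0)
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  if (object@perimeter <= 0) msg <- c(msg, "perimeter must be > 0")
  if (object@nSegments < 1L) msg <- c(msg, "nSegments must be >= 1")
  if (length(msg)) msg else TRUE
})
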