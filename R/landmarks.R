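# Landmark placement along the OC and IC face arcs.
#
# All landmark rules are arc-length fractions measured in the lateral-view
# plane: the OC distal boundary sits at 2/3 of the arc from PB_OC to
# DB_OFT(OC), the IC distal boundary at 1/2 of the arc from PB_IC to
# DB_OFT(IC), and the named Points I-IV are fractional positions along arcs
# or straight connecting segments, with different constructions at 48 hpf
# and 36-37 hpf.

.checkCellDiameter <- function(cellDiameter, ocLen) {
  if (cellDiameter < 0) stop("cell diameter must be >= 0")
  if (cellDiameter >= ocLen)
    stop(sprintf("cell diameter (%.1f um) must be smaller than the OC arc length (%.1f um)",
                 cellDiameter, ocLen))
}

#' Locate OC/IC landmarks for a 48 hpf ventricle
#'
#' PB_OC is one cell diameter from the AVC along the OC arc; DB_OC sits at
#' 2/3 of the arc from PB_OC to DB_OFT(OC). PB_IC is at the AVC; DB_IC at
#' 1/2 of the arc from PB_IC to DB_OFT(IC). Point I is the OC-arc midpoint
#' between PB_OC and DB_OC; Point II lies at 1/3 of the straight segment
#' from PB_IC towards Point I; Point III is the straight-line midpoint of
#' DB_IC and DB_OC.
#'
#' @param heart a \linkS4class{HeartModel}.
#' @param cellDiameter offset (um) of PB_OC from the AVC; defaults to the
#'   heart's typical cell diameter.
#' @return an \linkS4class{ArcLandmarks}.
#' @examples
#' lm <- locateLandmarks48(heartModel("48"))
#' lm@dbOc - (lm@pbOc + 2/3 * (lm@dbOftOc - lm@pbOc))  # 0 by construction
#' @export
locateLandmarks48 <- function(heart, cellDiameter = heart@cellDiameterTypical) {
  oc <- ocArc(heart); ic <- icArc(heart)
  .checkCellDiameter(cellDiameter, oc$length)
  pbOc <- cellDiameter
  dbOftOc <- oc$length
  dbOc <- pbOc + (2 / 3) * (dbOftOc - pbOc)
  pbIc <- 0
  dbOftIc <- ic$length
  dbIc <- pbIc + 0.5 * (dbOftIc - pbIc)
  pI <- arcPoint(oc, (pbOc + dbOc) / 2)
  pbIcPt <- arcPoint(ic, pbIc)
  pII <- pbIcPt + (pI - pbIcPt) / 3
  dbIcPt <- arcPoint(ic, dbIc)
  dbOcPt <- arcPoint(oc, dbOc)
  pIII <- (dbIcPt + dbOcPt) / 2
  methods::new("ArcLandmarks", stage = "48",
               pbOc = pbOc, dbOc = dbOc, dbOftOc = dbOftOc,
               pbIc = pbIc, dbIc = dbIc, dbOftIc = dbOftIc,
               points = list(I = pI, II = pII, III = pIII),
               arcPoints = list(pbOc = arcPoint(oc, pbOc), dbOc = dbOcPt,
                                pbIc = pbIcPt, dbIc = dbIcPt,
                                dbOftOc = arcPoint(oc, dbOftOc),
                                dbOftIc = arcPoint(ic, dbOftIc)),
               ocArc = oc, icArc = ic)
}

#' Locate OC/IC landmarks for a 36-37 hpf ventricle
#'
#' The less-contoured early ventricle uses straight medial borders: Points I
#' and II sit at 1/3 and 2/3 of the segment from PB_OC to PB_IC, and Points
#' III and IV at 1/3 and 2/3 of the segment from DB_OC to DB_IC. DB_OC and
#' DB_IC follow the same arc fractions as at 48 hpf.
#'
#' @inheritParams locateLandmarks48
#' @return an \linkS4class{ArcLandmarks} with points I-IV.
#' @export
locateLandmarks36 <- function(heart, cellDiameter = heart@cellDiameterTypical) {
  oc <- ocArc(heart); ic <- icArc(heart)
  .checkCellDiameter(cellDiameter, oc$length)
  pbOc <- cellDiameter
  dbOftOc <- oc$length
  dbOc <- pbOc + (2 / 3) * (dbOftOc - pbOc)
  pbIc <- 0
  dbOftIc <- ic$length
  dbIc <- pbIc + 0.5 * (dbOftIc - pbIc)
  pbOcPt <- arcPoint(oc, pbOc); pbIcPt <- arcPoint(ic, pbIc)
  dbOcPt <- arcPoint(oc, dbOc); dbIcPt <- arcPoint(ic, dbIc)
  pI <- pbOcPt + (pbIcPt - pbOcPt) / 3
  pII <- pbOcPt + 2 * (pbIcPt - pbOcPt) / 3
  pIII <- dbOcPt + (dbIcPt - dbOcPt) / 3
  pIV <- dbOcPt + 2 * (dbIcPt - dbOcPt) / 3
  methods::new("ArcLandmarks", stage = stageOf(heart),
               pbOc = pbOc, dbOc = dbOc, dbOftOc = dbOftOc,
               pbIc = pbIc, dbIc = dbIc, dbOftIc = dbOftIc,
               points = list(I = pI, II = pII, III = pIII, IV = pIV),
               arcPoints = list(pbOc = pbOcPt, dbOc = dbOcPt,
                                pbIc = pbIcPt, dbIc = dbIcPt,
                                dbOftOc = arcPoint(oc, dbOftOc),
                                dbOftIc = arcPoint(ic, dbOftIc)),
               ocArc = oc, icArc = ic)
}

#' Locate landmarks for a heart at its own stage
#' @inheritParams locateLandmarks48
#' @export
locateLandmarks <- function(heart, cellDiameter = heart@cellDiameterTypical) {
  if (stageOf(heart) == "48") locateLandmarks48(heart, cellDiameter)
  else locateLandmarks36(heart, cellDiameter)
}
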