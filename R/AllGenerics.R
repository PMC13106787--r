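# Generics and show methods.

#' @export
setGeneric("ocArc", function(object, ...) standardGeneric("ocArc"))
#' @export
setGeneric("icArc", function(object, ...) standardGeneric("icArc"))
#' @export
setGeneric("stageOf", function(object) standardGeneric("stageOf"))
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))
#' @export
setGeneric("embryoId", function(object) standardGeneric("embryoId"))
#' @export
setGeneric("trueRegion", function(object) standardGeneric("trueRegion"))
#' @export
setGeneric("apicalOutline", function(object) standardGeneric("apicalOutline"))
#' @export
setGeneric("basalOutline", function(object) standardGeneric("basalOutline"))
#' @export
setGeneric("membraneTruth", function(object) standardGeneric("membraneTruth"))
#' @export
setGeneric("neighborIds", function(object) standardGeneric("neighborIds"))
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @export
setGeneric("regionOf", function(object, pts) standardGeneric("regionOf"))

setMethod("stageOf", "HeartModel", function(object) object@stage)
setMethod("stageOf", "ArcLandmarks", function(object) object@stage)
setMethod("stageOf", "RegionBoundaries", function(object) object@stage)
setMethod("cellId", "Cardiomyocyte", function(object) object@cellId)
setMethod("cellId", "CrossSectionImage", function(object) object@cellId)
setMethod("embryoId", "Cardiomyocyte", function(object) object@embryoId)
setMethod("trueRegion", "Cardiomyocyte", function(object) object@trueRegion)
setMethod("apicalOutline", "Cardiomyocyte", function(object) object@apicalOutline)
setMethod("basalOutline", "Cardiomyocyte", function(object) object@basalOutline)
setMethod("membraneTruth", "Cardiomyocyte", function(object) object@membraneTruth)
setMethod("neighborIds", "Cardiomyocyte", function(object) object@neighbors)
setMethod("imageData", "CrossSectionImage", function(object) object@data)
setMethod("pixelSize", "CrossSectionImage", function(object) object@pixelSize)

setMethod("show", "HeartModel", function(object) {
  cat(sprintf("HeartModel (%s hpf)\n", object@stage))
  cat(sprintf("  bend radius %.1f um, tube radius %.1f um, bend angle %.3f rad\n",
              object@bendRadius, object@tubeRadius, object@bendAngle))
  cat(sprintf("  OC arc %.1f um, IC arc %.1f um\n",
              (object@bendRadius + object@tubeRadius) * object@bendAngle,
              (object@bendRadius - object@tubeRadius) * object@bendAngle))
})

setMethod("show", "Cardiomyocyte", function(object) {
  cat(sprintf("Cardiomyocyte %s (embryo %s)\n", object@cellId, object@embryoId))
  cat(sprintf("  region %s, clone %s, genotype %s, %d outline vertices\n",
              object@trueRegion, object@cloneLabel, object@genotypeLabel,
              nrow(object@apicalOutline)))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig (%s hpf, seed %d)\n", object@stage,
              as.integer(object@seed)))
  cat(sprintf("  cells: OC %d, IC %d, neither %d\n",
              object@cellCounts[["OC"]], object@cellCounts[["IC"]],
              object@cellCounts[["neither"]]))
  cat(sprintf("  OC apical area %.0f +/- %.0f um^2; noise SD %.1f\n",
              object@areaMean[["OC"]], object@areaSD[["OC"]], object@noiseSD))
})

setMethod("show", "ArcLandmarks", function(object) {
  cat(sprintf("ArcLandmarks (%s hpf)\n", object@stage))
  cat(sprintf("  OC arc: PB %.2f, DB %.2f, DB_OFT %.2f um\n",
              object@pbOc, object@dbOc, object@dbOftOc))
  cat(sprintf("  IC arc: PB %.2f, DB %.2f, DB_OFT %.2f um\n",
              object@pbIc, object@dbIc, object@dbOftIc))
  cat("  points:", paste(names(object@points), collapse = ", "), "\n")
})

setMethod("show", "CrossSectionImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("CrossSectionImage %s axis %s: %d x %d px, %d channels, %.2f um/px\n",
              object@cellId, object@axis, d[2], d[1], d[3], object@pixelSize))
})

setMethod("show", "ApicalTrace", function(object) {
  cat(sprintf("ApicalTrace: area %.2f um^2, perimeter %.2f um, %d segment(s)\n",
              object@area, object@perimeter, object@nSegments))
})
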