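# Readers and writers: CSV tables with metadata headers and schema
# validation, heart geometry JSON, flattened cell tables, and multi-page
# TIFF cross-sections (channel-major) with a JSON sidecar for calibration
# and ground-truth polylines.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a data.frame as CSV with a metadata header
#'
#' Metadata lines are prefixed with '#' (key: value); numeric columns are
#' serialized at full double precision so a write/read round trip is
#' lossless.
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named list/vector of metadata values.
#' @export
writeTableWithMeta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
}

#' Read a CSV written by \code{\link{writeTableWithMeta}}
#'
#' @param path input path.
#' @param schema optional schema from \code{\link{tableSchema}}; violations
#'   raise an error listing the offending columns and rows.
#' @return data.frame with attribute "meta" (named character vector).
#' @export
readTableWithMeta <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  metaIdx <- grep("^#", lines)
  metaIdx <- metaIdx[metaIdx == seq_along(metaIdx)]  # leading block only
  meta <- character(0)
  if (length(metaIdx)) {
    mm <- sub("^#\\s*", "", lines[metaIdx])
    keys <- sub(":.*$", "", mm)
    vals <- sub("^[^:]*:\\s*", "", mm)
    meta <- stats::setNames(vals, keys)
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), metaIdx)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) validateSchema(df, schema)
  attr(df, "meta") <- meta
  df
}

#' Declare a table schema
#'
#' @param ... column specifications: each a list with elements \code{type}
#'   ("numeric", "integer" or "character") and optional \code{min} /
#'   \code{max} bounds, named by column.
#' @return schema object for \code{\link{validateSchema}}.
#' @export
tableSchema <- function(...) {
  cols <- list(...)
  stopifnot(length(names(cols)) == length(cols))
  structure(cols, class = "tableSchema")
}

#' Validate a data.frame against a schema
#'
#' Unknown columns are preserved and ignored; declared columns must exist,
#' have the right type, and respect bounds.
#'
#' @param df data.frame.
#' @param schema from \code{\link{tableSchema}}.
#' @return invisibly TRUE; errors describe every violation found.
#' @export
validateSchema <- function(df, schema) {
  probs <- character(0)
  for (nm in names(schema)) {
    spec <- schema[[nm]]
    if (!nm %in% names(df)) { probs <- c(probs, sprintf("missing column '%s'", nm)); next }
    v <- df[[nm]]
    ok <- switch(spec$type, numeric = is.numeric(v),
                 integer = is.numeric(v) && all(v == round(v), na.rm = TRUE),
                 character = is.character(v), TRUE)
    if (!ok) { probs <- c(probs, sprintf("column '%s' is not %s", nm, spec$type)); next }
    if (!is.null(spec$min)) {
      bad <- which(v < spec$min)
      if (length(bad)) probs <- c(probs, sprintf(
        "column '%s' below %s in row(s) %s", nm, spec$min,
        paste(utils::head(bad, 5), collapse = ",")))
    }
    if (!is.null(spec$max)) {
      bad <- which(v > spec$max)
      if (length(bad)) probs <- c(probs, sprintf(
        "column '%s' above %s in row(s) %s", nm, spec$max,
        paste(utils::head(bad, 5), collapse = ",")))
    }
  }
  if (length(probs)) stop("schema violations: ", paste(probs, collapse = "; "))
  invisible(TRUE)
}

#' Schema of morphometrics.csv
#' @export
morphometricsSchema <- function() {
  tableSchema(cell_id = list(type = "character"),
              embryo_id = list(type = "character"),
              region = list(type = "character"),
              apical_area = list(type = "numeric", min = 0),
              circularity = list(type = "numeric", min = 0, max = 1 + 1e-6),
              apicobasal_length = list(type = "numeric", min = 0),
              volume = list(type = "numeric", min = 0))
}

.outlineToString <- function(m) {
  paste(apply(m, 1, function(r) paste(.fmtNum(r), collapse = " ")), collapse = ";")
}
.stringToOutline <- function(s) {
  rows <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], " ", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Flatten cells into a data.frame (one row per cell)
#'
#' Outlines are serialized as "x y z;x y z;..." strings, neighbours as
#' comma-separated ids and membrane truth as one column per channel/domain.
#'
#' @param cells list of \linkS4class{Cardiomyocyte}.
#' @return data.frame.
#' @export
cellsToTable <- function(cells) {
  rows <- lapply(cells, function(cl) {
    base <- data.frame(cell_id = cl@cellId, embryo_id = cl@embryoId,
                       true_region = cl@trueRegion,
                       center_s = cl@center[[1]], center_theta = cl@center[[2]],
                       clone_label = cl@cloneLabel,
                       genotype_label = cl@genotypeLabel,
                       orientation_axis = cl@orientation$axis,
                       orientation_angle = cl@orientation$angle,
                       apical_outline = .outlineToString(cl@apicalOutline),
                       basal_outline = .outlineToString(cl@basalOutline),
                       neighbors = paste(cl@neighbors, collapse = ","),
                       stringsAsFactors = FALSE, check.names = FALSE)
    for (i in 1:4) base[[paste0("wall_height_", i)]] <- cl@wallHeights[i]
    for (ch in names(cl@membraneTruth))
      for (dm in names(cl@membraneTruth[[ch]]))
        base[[paste("truth", ch, dm, sep = "_")]] <- cl@membraneTruth[[ch]][[dm]]
    base
  })
  do.call(rbind, rows)
}

#' Rebuild cells from a flattened table
#' @param df data.frame from \code{\link{cellsToTable}}.
#' @return list of \linkS4class{Cardiomyocyte}.
#' @export
tableToCells <- function(df) {
  truthCols <- grep("^truth_", names(df), value = TRUE)
  chans <- unique(sub("^truth_([^_]+)_.*$", "\\1", truthCols))
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    truth <- lapply(chans, function(ch) {
      doms <- c("basal", "apical", paste0("lateral", 1:4))
      stats::setNames(vapply(doms, function(dm)
        r[[paste("truth", ch, dm, sep = "_")]], numeric(1)), doms)
    })
    names(truth) <- chans
    nb <- if (is.na(r$neighbors) || r$neighbors == "") character(0) else
      strsplit(r$neighbors, ",", fixed = TRUE)[[1]]
    methods::new("Cardiomyocyte", cellId = r$cell_id, embryoId = r$embryo_id,
                 trueRegion = r$true_region,
                 center = c(s = r$center_s, theta = r$center_theta),
                 apicalOutline = .stringToOutline(r$apical_outline),
                 basalOutline = .stringToOutline(r$basal_outline),
                 wallHeights = c(r$wall_height_1, r$wall_height_2,
                                 r$wall_height_3, r$wall_height_4),
                 orientation = list(axis = r$orientation_axis,
                                    angle = r$orientation_angle),
                 cloneLabel = r$clone_label, genotypeLabel = r$genotype_label,
                 membraneTruth = truth, neighbors = nb)
  })
}

#' Write heart geometry (plus config echo) as JSON
#'
#' @param heart a \linkS4class{HeartModel}.
#' @param path output path.
#' @param config optional \linkS4class{GeneratorConfig} echoed into the file.
#' @export
writeHeartJson <- function(heart, path, config = NULL) {
  obj <- list(stage = heart@stage, bend_radius = heart@bendRadius,
              tube_radius = heart@tubeRadius, bend_angle = heart@bendAngle,
              origin = heart@origin, phase = heart@phase,
              cell_diameter_typical = heart@cellDiameterTypical,
              oft_boundaries = as.list(oftBoundaries(heart)))
  if (!is.null(config)) obj$config <- .configToList(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read heart geometry JSON
#' @param path input path.
#' @return list(heart = HeartModel, config = list or NULL).
#' @export
readHeartJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  heart <- heartModel(obj$stage, obj$bend_radius, obj$tube_radius,
                      obj$bend_angle, obj$cell_diameter_typical,
                      origin = obj$origin, phase = obj$phase)
  list(heart = heart, config = obj$config)
}

.configToList <- function(config) {
  nms <- methods::slotNames(methods::is(config)[1])
  out <- lapply(nms, function(nm) slot(config, nm))
  names(out) <- nms
  out
}

#' Stable hash of a configuration
#' @param config a GeneratorConfig (or any serialisable object).
#' @return md5 string.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  obj <- if (methods::isVirtualClass(class(config)) || isS4(config))
    .configToList(config) else config
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a cross-section image as multi-page TIFF plus JSON sidecar
#'
#' Pages are channel-major 32-bit float; intensities are rescaled to [0, 1]
#' by the stored scale factor (the image maximum), recorded with the pixel
#' size, channel names, axis and ground-truth polylines in
#' \code{<path>.json}.
#'
#' @param image a \linkS4class{CrossSectionImage}.
#' @param path output .tif path.
#' @export
writeCrossSectionTiff <- function(image, path) {
  scale <- max(image@data, 1e-12)
  pages <- lapply(seq_along(image@channels), function(k)
    image@data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  side <- list(pixel_size = image@pixelSize, axis = image@axis,
               channels = image@channels, scale = scale,
               cell_id = image@cellId,
               polylines = lapply(image@polylines, function(m)
                 list(x = m[, 1], y = m[, 2])))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cross-section TIFF written by \code{\link{writeCrossSectionTiff}}
#' @param path .tif path (sidecar \code{<path>.json} must exist).
#' @return a \linkS4class{CrossSectionImage}.
#' @export
readCrossSectionTiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(side$channels))
    stop(sprintf("expected %d channel pages (channel-major), found %d",
                 length(side$channels), length(pages)))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(0, dim = c(h, w, length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]] * side$scale
  polylines <- lapply(side$polylines, function(p) cbind(p$x, p$y))
  methods::new("CrossSectionImage", data = data,
               channels = side$channels, pixelSize = side$pixel_size,
               axis = side$axis, polylines = polylines,
               cellId = side$cell_id)
}
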