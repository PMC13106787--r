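# Membrane-band intensity profiling, myocardium summaries, outlier
# screening and 1-10 rfu min-max normalization.

#' Mean intensity in a membrane band
#'
#' Emulates the wide-line trace "just inside the membrane": the band is the
#' set of pixels whose centres lie within \code{width/2} of the polyline, on
#' its interior side, after trimming \code{cornerExclusion} micrometres from
#' each polyline end so that corner pixels (where lateral and basal/apical
#' membranes meet) are excluded.
#'
#' @param image a \linkS4class{CrossSectionImage}.
#' @param polyline 2-column matrix in pixel coordinates, or the name of one
#'   of the image's stored polylines ("basal", "apical", "lateral-left",
#'   "lateral-right").
#' @param channel channel name or index.
#' @param width band width (um), default 1.0.
#' @param cornerExclusion trim (um) from each polyline end, default 1.0.
#' @param interiorPoint optional 2D point (pixel coords) marking the cell
#'   interior; defaults to the centroid of the stored polylines.
#' @return list with \code{mean}, \code{pixels} (n x 2 matrix of col/row
#'   indices, for auditing) and \code{values}.
#' @export
bandMean <- function(image, polyline, channel, width = 1.0,
                     cornerExclusion = 1.0, interiorPoint = NULL) {
  if (is.character(polyline) && length(polyline) == 1L) {
    if (!polyline %in% names(image@polylines))
      stop(sprintf("no stored polyline '%s'", polyline))
    polyline <- image@polylines[[polyline]]
  }
  if (is.character(channel)) channel <- match(channel, image@channels)
  if (is.na(channel)) stop("unknown channel")
  ps <- image@pixelSize
  pl <- polyline * ps  # to um
  pl <- .trimPolyline(pl, cornerExclusion)
  if (is.null(pl)) stop("polyline empty after corner trimming")
  if (is.null(interiorPoint)) {
    allp <- do.call(rbind, image@polylines)
    interiorPoint <- colMeans(allp)
  }
  interior <- interiorPoint * ps
  d <- dim(image@data)
  h <- d[1]; w <- d[2]
  cx <- (seq_len(w) - 0.5) * ps
  cy <- (seq_len(h) - 0.5) * ps
  gx <- matrix(cx, h, w, byrow = TRUE)
  gy <- matrix(cy, h, w)
  inBand <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(pl) - 1L)) {
    p1 <- pl[k, ]; p2 <- pl[k + 1L, ]
    dseg <- p2 - p1
    len2 <- sum(dseg^2)
    if (len2 < 1e-12) next
    t <- ((gx - p1[1]) * dseg[1] + (gy - p1[2]) * dseg[2]) / len2
    onSeg <- t >= 0 & t <= 1
    # signed offset: positive towards the interior side
    crossv <- (gx - p1[1]) * dseg[2] - (gy - p1[2]) * dseg[1]
    sgn <- sign((interior[1] - p1[1]) * dseg[2] - (interior[2] - p1[2]) * dseg[1])
    off <- crossv * sgn / sqrt(len2)
    inBand <- inBand | (onSeg & off >= 0 & off <= width / 2)
  }
  if (!any(inBand)) stop("no pixels in band after trimming")
  vals <- image@data[, , channel][inBand]
  idx <- which(inBand, arr.ind = TRUE)
  list(mean = mean(vals), pixels = cbind(col = idx[, 2], row = idx[, 1]),
       values = vals)
}

# trim `trim` um from each end of a polyline (um coords); NULL if nothing left
.trimPolyline <- function(pl, trim) {
  if (trim <= 0) return(pl)
  seglen <- sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2))
  total <- sum(seglen)
  if (total <= 2 * trim) return(NULL)
  cum <- c(0, cumsum(seglen))
  atLength <- function(s) {
    i <- max(which(cum <= s + 1e-12)); i <- min(i, nrow(pl) - 1L)
    t <- (s - cum[i]) / seglen[i]
    pl[i, ] + t * (pl[i + 1L, ] - pl[i, ])
  }
  s0 <- trim; s1 <- total - trim
  keep <- which(cum > s0 & cum < s1)
  rbind(atLength(s0), pl[keep, , drop = FALSE], atLength(s1))
}

#' Membrane-domain intensity profile of one cell
#'
#' Takes the two cross-section images of a cell (X and Y), measures the
#' eight band means per channel (2 basal, 2 apical, 4 lateral), reduces them
#' to the three domain means, and derives the domain percentages and the
#' basal ratio mean_basal / (mean_apical + mean_lateral).
#'
#' @param imageX,imageY \linkS4class{CrossSectionImage}s of the same cell.
#' @param width,cornerExclusion band geometry (um); defaults 1.0 and 1.0.
#' @param channels channels to profile; default all non-membrane channels.
#' @return data.frame with one row per channel: cell_id, channel,
#'   mean_basal, mean_apical, mean_lateral, pct_basal, pct_lateral,
#'   pct_apical, basal_ratio, flagged.
#' @export
profileCell <- function(imageX, imageY, width = 1.0, cornerExclusion = 1.0,
                        channels = NULL) {
  if (missing(imageY) || is.null(imageY)) stop("both X and Y sections are required")
  if (imageX@cellId != imageY@cellId)
    stop("sections belong to different cells")
  if (is.null(channels))
    channels <- setdiff(imageX@channels, "membrane")
  needed <- c("basal", "apical", "lateral-left", "lateral-right")
  for (img in list(imageX, imageY))
    if (!all(needed %in% names(img@polylines)))
      stop("section is missing membrane polylines")
  rows <- lapply(channels, function(ch) {
    bands <- function(img) vapply(needed, function(nm)
      bandMean(img, nm, ch, width, cornerExclusion)$mean, numeric(1))
    bx <- bands(imageX); by <- bands(imageY)
    meanBasal <- mean(c(bx[["basal"]], by[["basal"]]))
    meanApical <- mean(c(bx[["apical"]], by[["apical"]]))
    meanLateral <- mean(c(bx[["lateral-left"]], bx[["lateral-right"]],
                          by[["lateral-left"]], by[["lateral-right"]]))
    tot <- meanBasal + meanApical + meanLateral
    if (tot <= 0) {
      return(data.frame(cell_id = imageX@cellId, channel = ch,
                        mean_basal = meanBasal, mean_apical = meanApical,
                        mean_lateral = meanLateral, pct_basal = NA_real_,
                        pct_lateral = NA_real_, pct_apical = NA_real_,
                        basal_ratio = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    data.frame(cell_id = imageX@cellId, channel = ch,
               mean_basal = meanBasal, mean_apical = meanApical,
               mean_lateral = meanLateral,
               pct_basal = 100 * meanBasal / tot,
               pct_lateral = 100 * meanLateral / tot,
               pct_apical = 100 * meanApical / tot,
               basal_ratio = meanBasal / (meanApical + meanLateral),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean myocardial intensity of one ventricle image
#'
#' @param image matrix, h x w x channel array, or
#'   \linkS4class{CrossSectionImage}.
#' @param mask logical matrix marking myocardial pixels.
#' @param channel channel index or name (for multi-channel input).
#' @return mean intensity over masked pixels.
#' @export
myocardiumMean <- function(image, mask, channel = 1L) {
  if (methods::is(image, "CrossSectionImage")) {
    if (is.character(channel)) channel <- match(channel, image@channels)
    image <- image@data[, , channel]
  } else if (length(dim(image)) == 3) {
    image <- image[, , channel]
  }
  if (!any(mask)) stop("empty myocardium mask")
  mean(image[mask])
}

#' Per-embryo myocardium summary with outlier screening and rfu scaling
#'
#' Computes (or accepts) one mean myocardial intensity per embryo, screens
#' each replicate's values for outliers, and min-max rescales each
#' replicate's non-outlier values to the 1-10 rfu scale.
#'
#' @param values numeric per-embryo mean intensities (raw units).
#' @param embryoIds,replicateIds character vectors parallel to
#'   \code{values}.
#' @param outlierRule passed to \code{\link{screenOutliers}}.
#' @return data.frame: embryo_id, replicate_id, raw, outlier_flag, rfu
#'   (NA for flagged values).
#' @export
summarizeVentricles <- function(values, embryoIds, replicateIds,
                                outlierRule = "tukey") {
  stopifnot(length(values) == length(embryoIds),
            length(values) == length(replicateIds))
  out <- data.frame(embryo_id = embryoIds, replicate_id = replicateIds,
                    raw = values, outlier_flag = FALSE, rfu = NA_real_,
                    stringsAsFactors = FALSE)
  for (rep in unique(replicateIds)) {
    i <- which(out$replicate_id == rep)
    out$outlier_flag[i] <- screenOutliers(out$raw[i], rule = outlierRule)
    keep <- i[!out$outlier_flag[i]]
    if (length(keep) >= 2 && length(unique(out$raw[keep])) >= 2)
      out$rfu[keep] <- minmaxRfu(out$raw[keep])
  }
  out
}

#' Flag outliers in a group of values
#'
#' Default rule: Tukey fences, flagging values outside
#' [Q1 - k IQR, Q3 + k IQR] with k = 1.5. Flagged values are meant to be
#' excluded from downstream statistics but never deleted from outputs.
#'
#' @param values numeric vector.
#' @param rule "tukey" (only built-in rule) or a function mapping values to
#'   a logical flag vector.
#' @param k fence multiplier for the Tukey rule.
#' @return logical vector of flags.
#' @export
screenOutliers <- function(values, rule = "tukey", k = 1.5) {
  if (length(values) < 3) {
    warning("fewer than 3 values; no outlier screening performed")
    return(rep(FALSE, length(values)))
  }
  if (is.function(rule)) return(rule(values))
  if (!identical(rule, "tukey")) stop("unknown outlier rule")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Min-max normalization to the 1-10 rfu scale
#'
#' x -> 1 + 9 (x - min) / (max - min): each replicate's smallest value maps
#' to 1 rfu and largest to 10 rfu, preserving order and relative spacing.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return normalized values on [1, 10].
#' @export
minmaxRfu <- function(values) {
  if (length(values) < 2) stop("min-max normalization needs at least 2 values")
  lo <- min(values); hi <- max(values)
  if (hi == lo) stop("min-max normalization undefined when all values are equal")
  1 + 9 * (values - lo) / (hi - lo)
}
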