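# Seeded synthetic-ventricle generator.
#
# The generator is the package's study-conditions module: it emulates a
# laterally mounted embryonic ventricle as a torus-sector surface tiled with
# labelled prism cells whose apical areas, elongations, apicobasal lengths
# and membrane-domain intensity fractions are drawn from configured
# per-region distributions. The wild-type 48 hpf OC apical-area parameters
# (mean 142 um^2, SD 43 um^2) and the regional cell counts (~55 OC, ~28 IC)
# reproduce the reported reference conditions; all other defaults are free
# modelling choices documented in the methods vignette.

#' Build a generator configuration
#'
#' @param stage "36", "37" or "48".
#' @param cellCounts,areaMean,areaSD,elongMean,elongSD,heightMean,heightSD
#'   named per-region (OC, IC, neither) parameters; see slot docs in
#'   \linkS4class{GeneratorConfig}.
#' @param fractions per-region list of per-channel (basal, lateral, apical)
#'   fraction triplets summing to 1.
#' @param intensityScale mean per-cell total intensity (arbitrary units).
#' @param noiseSD,background imaging noise SD and background fraction of the
#'   peak truth intensity.
#' @param pixelSize um/px for rendered sections.
#' @param bendRadius,tubeRadius,bendAngle,cellDiameterTypical heart geometry.
#' @param donorFraction fraction of cells marked as donor clones.
#' @param genotype,embryoId labels stamped on generated cells.
#' @param seed RNG seed.
#' @return a validated \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(stage = "48",
    cellCounts = c(OC = 55, IC = 28, neither = 60),
    areaMean = c(OC = 142, IC = 80, neither = 110),
    areaSD = c(OC = 43, IC = 24, neither = 33),
    elongMean = c(OC = 2.2, IC = 1.3, neither = 1.6),
    elongSD = c(OC = 0.35, IC = 0.15, neither = 0.25),
    heightMean = c(OC = 4.5, IC = 8, neither = 6),
    heightSD = c(OC = 0.7, IC = 1.2, neither = 1),
    fractions = list(
      OC = list("F-actin" = c(basal = 0.45, lateral = 0.35, apical = 0.20),
                "pMyosin" = c(basal = 0.50, lateral = 0.30, apical = 0.20)),
      IC = list("F-actin" = c(basal = 0.30, lateral = 0.40, apical = 0.30),
                "pMyosin" = c(basal = 0.30, lateral = 0.40, apical = 0.30)),
      neither = list("F-actin" = c(basal = 0.35, lateral = 0.38, apical = 0.27),
                     "pMyosin" = c(basal = 0.35, lateral = 0.38, apical = 0.27))),
    intensityScale = 150, noiseSD = 8, background = 0.05, pixelSize = 0.3,
    bendRadius = 130, tubeRadius = 65, bendAngle = 1.4,
    cellDiameterTypical = 10, donorFraction = 0, genotype = "WT",
    embryoId = "embryo1", seed = 1) {
  methods::new("GeneratorConfig", stage = as.character(stage),
               cellCounts = cellCounts, areaMean = areaMean, areaSD = areaSD,
               elongMean = elongMean, elongSD = elongSD,
               heightMean = heightMean, heightSD = heightSD,
               fractions = fractions, intensityScale = intensityScale,
               noiseSD = noiseSD, background = background,
               pixelSize = pixelSize, bendRadius = bendRadius,
               tubeRadius = tubeRadius, bendAngle = bendAngle,
               cellDiameterTypical = cellDiameterTypical,
               donorFraction = donorFraction, genotype = genotype,
               embryoId = embryoId, seed = seed)
}

#' Stratified draws from a truncated normal distribution
#'
#' Draws n values from N(mean, sd) truncated at > 0 using permuted stratified
#' inverse-CDF sampling: each draw's marginal distribution is exactly the
#' truncated normal, while cohort moments concentrate faster than iid
#' sampling, so synthetic cohorts match their nominal moments at realistic n.
#' Call inside \code{withSeed} or after \code{set.seed} for determinism.
#'
#' @param n number of draws.
#' @param mean,sd distribution parameters (before truncation at 0).
#' @return numeric vector of n positive values.
#' @export
sampleTruncNormStratified <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  u <- (sample.int(n) - 1 + stats::runif(n)) / n
  stats::qnorm(lo + u * (1 - lo), mean, sd)
}

#' Surface chart coordinates of points on (or near) the heart surface
#'
#' Maps 3D points to the chart (s, c) = (phi * bendRadius, theta *
#' tubeRadius), an unrolled coordinate system in which neighbouring cells'
#' outlines can be compared without lateral-projection artefacts. theta is
#' unwrapped to (-pi, pi] around each point's own branch.
#'
#' @param heart a \linkS4class{HeartModel}.
#' @param pts n x 3 matrix.
#' @param thetaCenter optional angle (rad): theta is unwrapped to the branch
#'   centred on this value, so a polygon near the branch cut stays coherent.
#' @return n x 2 matrix of chart coordinates (um).
#' @export
chartCoordinates <- function(heart, pts, thetaCenter = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  dx <- pts[, 1] - heart@origin[1]
  dz <- pts[, 3] - heart@origin[2]
  phi <- atan2(dz, dx) - heart@phase
  phi <- ((phi + pi) %% (2 * pi)) - pi
  r <- sqrt(dx^2 + dz^2)
  theta <- atan2(pts[, 2], r - heart@bendRadius)
  theta <- thetaCenter + .wrapTheta(theta - thetaCenter)
  cbind(phi * heart@bendRadius, theta * heart@tubeRadius)
}

# Chart-space outline of an ellipse cell: centre (phi0, th0), semi-axes
# (a = circumferential/major before rotation, b = longitudinal/minor),
# rotated by `angle`. Physical offsets are converted through the local
# metric at the cell centre.
.ellipseChart <- function(Rb, rt, phi0, th0, a, b, angle, nv = 24L) {
  t <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  v <- a * cos(t); u <- b * sin(t)
  ur <- u * cos(angle) - v * sin(angle)   # physical longitudinal offset
  vr <- u * sin(angle) + v * cos(angle)   # physical circumferential offset
  dphi <- ur / (Rb + rt * cos(th0))
  cbind((phi0 + dphi) * Rb, (th0 + vr / rt) * rt)
}

# Do two convex-ish polygons overlap? Edge-crossing or containment test.
.polysOverlap <- function(P, Q) {
  if (any(pointInPolygon(P, Q)) || any(pointInPolygon(Q, P))) return(TRUE)
  n <- nrow(P); m <- nrow(Q)
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    p1 <- P[i, ]; p2 <- P[i2, ]
    for (j in seq_len(m)) {
      j2 <- if (j == m) 1L else j + 1L
      q1 <- Q[j, ]; q2 <- Q[j2, ]
      d1 <- cross2(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
      d2 <- cross2(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
      d3 <- cross2(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
      d4 <- cross2(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Generate a synthetic heart
#'
#' Builds the heart surface, delineates ground-truth OC/IC boundaries with
#' the package's own landmark rules, relaxes per-region seed points towards a
#' centroidal arrangement (Lloyd iterations via k-means on area-weighted
#' surface samples), and places one elongated prism cell per seed with an
#' apical outline of exactly the drawn area. Overlapping placements are
#' separated by a deterministic anisotropic push-apart pass followed by an
#' exact polygon-overlap resolution pass in the surface chart. Each cell's
#' true region is re-derived from its final outline against the ground-truth
#' boundaries with the half-body rule.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return list with elements \code{heart} (\linkS4class{HeartModel}),
#'   \code{cells} (list of \linkS4class{Cardiomyocyte}), \code{boundaries}
#'   (ground-truth \linkS4class{RegionBoundaries}) and \code{config}.
#' @examples
#' \donttest{
#' hd <- generateHeart(generatorConfig(seed = 1))
#' table(vapply(hd$cells, trueRegion, character(1)))
#' }
#' @export
generateHeart <- function(config) {
  methods::validObject(config)
  heart <- heartModel(config@stage, config@bendRadius, config@tubeRadius,
                      config@bendAngle, config@cellDiameterTypical)
  landmarks <- locateLandmarks(heart)
  boundaries <- buildRegionBoundaries(landmarks)
  Rb <- config@bendRadius; rt <- config@tubeRadius
  withSeed(config@seed, {
    # dense area-weighted surface sample classified by true region
    nS <- 6000L
    phi <- stats::runif(4 * nS, 0.015, config@bendAngle - 0.015)
    th <- stats::runif(4 * nS, 0, 2 * pi)
    keep <- stats::runif(4 * nS) < (Rb + rt * cos(th)) / (Rb + rt)
    phi <- phi[keep][seq_len(nS)]; th <- th[keep][seq_len(nS)]
    proj <- lateralProject(midsurfacePoint(heart, phi * Rb, th))
    regions <- regionOf(boundaries, proj)
    regionAreas <- .regionSurfaceAreas(heart, boundaries)
    params <- list()
    for (r in c("OC", "IC", "neither")) {
      m <- as.integer(config@cellCounts[[r]])
      need <- m * config@areaMean[[r]]
      if (need > 0.8 * regionAreas[[r]])
        stop(sprintf(paste0(
          "infeasible tiling: %d %s cells of mean area %.0f um^2 need ",
          "%.0f um^2 but the %s region offers only %.0f um^2 ",
          "(80%% packing limit)"),
          m, r, config@areaMean[[r]], need, r, regionAreas[[r]]))
      idx <- which(regions == r)
      if (length(idx) < m) stop(sprintf("region %s too sparse to seat %d cells", r, m))
      # centre the periodic theta chart on the region's own face so k-means
      # does not split clusters across the seam (OC face sits at theta = 0)
      thc <- if (r == "OC") .wrapTheta(th[idx]) else th[idx]
      P <- cbind(phi[idx] * Rb, thc * rt)
      km <- suppressWarnings(stats::kmeans(P, centers = m, iter.max = 30))
      areas <- sampleTruncNormStratified(m, config@areaMean[[r]], config@areaSD[[r]])
      elong <- pmax(1, stats::rnorm(m, config@elongMean[[r]], config@elongSD[[r]]))
      heights <- pmax(1, sampleTruncNormStratified(m, config@heightMean[[r]],
                                                   config@heightSD[[r]]))
      angles <- stats::rnorm(m, 0, 10 * pi / 180)
      scale <- stats::rlnorm(m, log(config@intensityScale), 0.2)
      params[[r]] <- data.frame(phi = km$centers[, 1] / Rb,
                                th = km$centers[, 2] / rt,
                                area = areas, elong = elong, height = heights,
                                angle = angles, intensity = scale,
                                hint = r, stringsAsFactors = FALSE)
    }
    pp <- do.call(rbind, params)
    n <- nrow(pp)
    b <- sqrt(pp$area / (pi * pp$elong))
    a <- b * pp$elong
    ctr <- cbind(pp$phi, pp$th)
    # phase 1: anisotropic push-apart of near-axis-aligned ellipses
    for (iter in 1:15) {
      moved <- FALSE
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        dth <- .wrapTheta(ctr[j, 2] - ctr[i, 2])
        thm <- ctr[i, 2] + dth / 2
        du <- (ctr[j, 1] - ctr[i, 1]) * (Rb + rt * cos(thm))
        dv <- dth * rt
        dEff <- sqrt((du / (b[i] + b[j]))^2 + (dv / (a[i] + a[j]))^2)
        if (dEff < 1 && dEff > 1e-9) {
          f <- 0.55 * (1 - dEff)
          stepU <- du * f; stepV <- dv * f
          ctr[i, 1] <- ctr[i, 1] - stepU / 2 / (Rb + rt * cos(thm))
          ctr[j, 1] <- ctr[j, 1] + stepU / 2 / (Rb + rt * cos(thm))
          ctr[i, 2] <- ctr[i, 2] - stepV / 2 / rt
          ctr[j, 2] <- ctr[j, 2] + stepV / 2 / rt
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    ctr[, 1] <- pmin(pmax(ctr[, 1], 0.015), config@bendAngle - 0.015)
    # phase 2: exact chart-polygon overlap resolution
    charts <- lapply(seq_len(n), function(i)
      .ellipseChart(Rb, rt, ctr[i, 1], ctr[i, 2], a[i], b[i], pp$angle[i]))
    rmax <- a
    for (iter in 1:25) {
      any2 <- FALSE
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        dth <- .wrapTheta(ctr[j, 2] - ctr[i, 2])
        thm <- ctr[i, 2] + dth / 2
        du <- (ctr[j, 1] - ctr[i, 1]) * (Rb + rt * cos(thm))
        dv <- dth * rt
        if (du^2 + dv^2 > (rmax[i] + rmax[j])^2) next
        Qj <- charts[[j]]
        Qj[, 2] <- Qj[, 2] - (ctr[j, 2] - ctr[i, 2] - dth) * rt
        if (.polysOverlap(charts[[i]], Qj)) {
          any2 <- TRUE
          d <- sqrt(du^2 + dv^2); if (d < 1e-9) { du <- 1; dv <- 0; d <- 1 }
          mv <- 0.45
          ctr[i, 1] <- ctr[i, 1] - mv * du / d / (Rb + rt * cos(thm))
          ctr[j, 1] <- ctr[j, 1] + mv * du / d / (Rb + rt * cos(thm))
          ctr[i, 2] <- ctr[i, 2] - mv * dv / d / rt
          ctr[j, 2] <- ctr[j, 2] + mv * dv / d / rt
          charts[[i]] <- .ellipseChart(Rb, rt, ctr[i, 1], ctr[i, 2], a[i],
                                       b[i], pp$angle[i])
          charts[[j]] <- .ellipseChart(Rb, rt, ctr[j, 1], ctr[j, 2], a[j],
                                       b[j], pp$angle[j])
        }
      }
      if (!any2) break
    }
    ctr[, 1] <- pmin(pmax(ctr[, 1], 0.015), config@bendAngle - 0.015)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      out[[i]] <- .buildCell(heart, config, boundaries,
                             id = sprintf("%s_c%03d", config@embryoId, i),
                             phiTheta = ctr[i, ], area = pp$area[i],
                             elong = pp$elong[i], height = pp$height[i],
                             angle = pp$angle[i], intensity = pp$intensity[i])
    }
    # phase 3: resolve residual overlaps of the final (rescaled) outlines,
    # compared in each cell's own theta branch of the surface chart
    charts3 <- lapply(seq_len(n), function(i)
      chartCoordinates(heart, out[[i]]@apicalOutline, thetaCenter = ctr[i, 2]))
    rebuild <- function(i) {
      out[[i]] <<- .buildCell(heart, config, boundaries,
                              id = sprintf("%s_c%03d", config@embryoId, i),
                              phiTheta = ctr[i, ], area = pp$area[i],
                              elong = pp$elong[i], height = pp$height[i],
                              angle = pp$angle[i], intensity = pp$intensity[i])
      charts3[[i]] <<- chartCoordinates(heart, out[[i]]@apicalOutline,
                                        thetaCenter = ctr[i, 2])
    }
    for (iter in 1:12) {
      clean <- TRUE
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        dth <- .wrapTheta(ctr[j, 2] - ctr[i, 2])
        thm <- ctr[i, 2] + dth / 2
        du <- (ctr[j, 1] - ctr[i, 1]) * (Rb + rt * cos(thm))
        dv <- dth * rt
        if (du^2 + dv^2 > (1.2 * (rmax[i] + rmax[j]))^2) next
        Qj <- charts3[[j]]
        Qj[, 2] <- Qj[, 2] - (ctr[j, 2] - ctr[i, 2] - dth) * rt
        if (.polysOverlap(charts3[[i]], Qj)) {
          clean <- FALSE
          d <- sqrt(du^2 + dv^2); if (d < 1e-9) { du <- 1; dv <- 0; d <- 1 }
          mv <- 0.4
          ctr[i, 1] <- ctr[i, 1] - mv * du / d / (Rb + rt * cos(thm))
          ctr[j, 1] <- ctr[j, 1] + mv * du / d / (Rb + rt * cos(thm))
          ctr[i, 2] <- ctr[i, 2] - mv * dv / d / rt
          ctr[j, 2] <- ctr[j, 2] + mv * dv / d / rt
          rebuild(i); rebuild(j)
        }
      }
      if (clean) break
    }
    if (!clean) warning("some apical outlines still overlap after relaxation")
    # neighbour graph: centres closer than 1.35 x summed major semi-axes
    ids <- vapply(out, cellId, character(1))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dth <- .wrapTheta(ctr[j, 2] - ctr[i, 2])
      thm <- ctr[i, 2] + dth / 2
      du <- (ctr[j, 1] - ctr[i, 1]) * (Rb + rt * cos(thm))
      dv <- dth * rt
      if (sqrt(du^2 + dv^2) < 1.35 * (a[i] + a[j]) / 2 + (b[i] + b[j]) / 2) {
        out[[i]]@neighbors <- c(out[[i]]@neighbors, ids[j])
        out[[j]]@neighbors <- c(out[[j]]@neighbors, ids[i])
      }
    }
    if (config@donorFraction > 0) {
      nd <- max(1L, round(config@donorFraction * n))
      don <- sample.int(n, nd)
      for (i in don) out[[i]]@cloneLabel <- "donor"
    }
    list(heart = heart, cells = out, boundaries = boundaries, config = config)
  })
}

# wrap an angular difference into (-pi, pi]
.wrapTheta <- function(d) ((d + pi) %% (2 * pi)) - pi

# surface areas of the true regions, by quadrature on a (phi, theta) grid
.regionSurfaceAreas <- function(heart, boundaries, nphi = 120L, nth = 120L) {
  Rb <- heart@bendRadius; rt <- heart@tubeRadius
  phis <- (seq_len(nphi) - 0.5) / nphi * heart@bendAngle
  ths <- (seq_len(nth) - 0.5) / nth * 2 * pi
  g <- expand.grid(phi = phis, th = ths)
  w <- rt * (heart@bendAngle / nphi) * (2 * pi / nth) * (Rb + rt * cos(g$th))
  proj <- lateralProject(midsurfacePoint(heart, g$phi * Rb, g$th))
  reg <- regionOf(boundaries, proj)
  c(OC = sum(w[reg == "OC"]), IC = sum(w[reg == "IC"]),
    neither = sum(w[reg == "neither"]))
}

# Build one prism cell at (phi, theta) with an apical outline whose
# best-fit-plane projected area (what the en-face snapshot measures) equals
# `area` exactly, via Newton rescaling of the surface ellipse.
.buildCell <- function(heart, config, boundaries, id, phiTheta, area, elong,
                       height, angle, intensity) {
  Rb <- heart@bendRadius; rt <- heart@tubeRadius
  phi0 <- phiTheta[1]; th0 <- phiTheta[2]
  t <- seq(0, 2 * pi, length.out = 25L)[-25L]
  b0 <- sqrt(area / (pi * elong))
  a0 <- b0 * elong
  mkOutline <- function(scl, radialOffset = 0) {
    v <- scl * a0 * cos(t)   # circumferential (theta) direction
    u <- scl * b0 * sin(t)   # longitudinal (phi) direction
    ur <- u * cos(angle) - v * sin(angle)
    vr <- u * sin(angle) + v * cos(angle)
    phi <- phi0 + ur / (Rb + rt * cos(th0))
    th <- th0 + vr / rt
    midsurfacePoint(heart, phi * Rb, th, radialOffset = radialOffset)
  }
  scl <- 1
  for (it in 1:10) {
    ap <- mkOutline(scl)
    got <- projectedPolygonArea(ap)
    if (abs(got - area) / area < 1e-10) break
    scl <- scl * sqrt(area / got)
  }
  apical <- mkOutline(scl)
  basal <- mkOutline(scl, radialOffset = height)
  region <- regionOf(boundaries, lateralProject(matrix(colMeans(apical), 1)))
  fr <- tryCatch(.regionFractions(boundaries, lateralProject(apical)),
                 error = function(e) c(OC = NA_real_, IC = NA_real_))
  if (!anyNA(fr))
    region <- if (fr[["IC"]] >= 0.5) "IC" else if (fr[["OC"]] >= 0.5) "OC" else "neither"
  truth <- lapply(config@fractions[[region]], function(f) {
    c(basal = 3 * intensity * f[["basal"]],
      apical = 3 * intensity * f[["apical"]],
      lateral1 = 3 * intensity * f[["lateral"]],
      lateral2 = 3 * intensity * f[["lateral"]],
      lateral3 = 3 * intensity * f[["lateral"]],
      lateral4 = 3 * intensity * f[["lateral"]])
  })
  methods::new("Cardiomyocyte", cellId = id, embryoId = config@embryoId,
               trueRegion = region, center = c(s = phi0 * Rb, theta = th0),
               apicalOutline = apical, basalOutline = basal,
               wallHeights = rep(height, 4),
               orientation = list(axis = if (abs(angle) < pi / 4)
                 "circumferential" else "longitudinal", angle = angle),
               cloneLabel = "host", genotypeLabel = config@genotype,
               membraneTruth = truth, neighbors = character(0))
}

#' Generate a population of cells across replicate synthetic hearts
#'
#' Convenience wrapper for cohort-level analyses: repeatedly generates
#' synthetic hearts (one embryo each, with seeds derived from the master
#' seed) until \code{n} cells of the requested region are collected.
#'
#' @param n number of cells wanted.
#' @param region "OC", "IC" or "neither".
#' @param config template \linkS4class{GeneratorConfig}; its per-region
#'   distributions define the population.
#' @param seed master seed; per-embryo seeds are derived from it.
#' @return list of \linkS4class{Cardiomyocyte} of length \code{n}.
#' @export
generateCellPopulation <- function(n, region = "OC", config = generatorConfig(),
                                   seed = config@seed) {
  cells <- list(); k <- 0L
  while (length(cells) < n) {
    k <- k + 1L
    cfg <- methods::initialize(config, seed = childSeed(seed, k),
                               embryoId = sprintf("embryo%02d", k))
    hd <- generateHeart(cfg)
    got <- Filter(function(c) trueRegion(c) == region, hd$cells)
    cells <- c(cells, got)
    if (k > 60) stop("unable to collect enough cells; check configuration")
  }
  cells[seq_len(n)]
}
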