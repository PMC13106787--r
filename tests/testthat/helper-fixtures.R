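# Shared fixtures. Expensive synthetic hearts are generated once per test
# session and cached.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

defaultHeart <- function() {
  cachedFixture("defaultHeart", generateHeart(generatorConfig(seed = 1)))
}

defaultAssignment <- function() {
  cachedFixture("defaultAssignment", {
    hd <- defaultHeart()
    assignCells(hd$cells, hd$boundaries)
  })
}

smallQuietConfig <- function(seed = 7) {
  generatorConfig(cellCounts = c(OC = 16, IC = 10, neither = 18),
                  noiseSD = 0, background = 0, seed = seed)
}

# a prism cell built directly from apical/basal outlines (test geometry)
prismCell <- function(apical, basal, heights = NULL, id = "cell1",
                      embryo = "e1", region = "OC",
                      truth = list(), neighbors = character(0),
                      clone = "host") {
  if (is.null(heights)) {
    heights <- rep(mean(sqrt(rowSums((apical[1:4, ] - basal[1:4, ])^2))), 4)
  }
  new("Cardiomyocyte", cellId = id, embryoId = embryo, trueRegion = region,
      center = c(s = 0, theta = 0), apicalOutline = apical,
      basalOutline = basal, wallHeights = heights,
      orientation = list(axis = "circumferential", angle = 0),
      cloneLabel = clone, genotypeLabel = "WT",
      membraneTruth = truth, neighbors = neighbors)
}

# upright cuboid cell: apical Lx x Ly at height h, basal congruent at 0
cuboidCell <- function(Lx = 10, Ly = 6, h = 5, id = "cuboid") {
  ap <- cbind(c(0, Lx, Lx, 0), c(0, 0, Ly, Ly), h)
  ba <- cbind(c(0, Lx, Lx, 0), c(0, 0, Ly, Ly), 0)
  prismCell(ap, ba, heights = rep(h, 4), id = id)
}

uniformTruth <- function(u, channels = c("F-actin", "pMyosin")) {
  doms <- c("basal", "apical", paste0("lateral", 1:4))
  stats::setNames(lapply(channels, function(ch)
    stats::setNames(rep(u, 6), doms)), channels)
}

# rectangle outline draped over a cylinder of radius R (surface test shape):
# arc half-angle `half` per side, axial length L, axis along y
drapedOutline <- function(R = 20, half = pi / 6, L = 12) {
  mk <- function(th, z) c(R * sin(th), z, R * cos(th))
  thetas <- seq(-half, half, length.out = 24)
  edge1 <- t(sapply(thetas, mk, z = 0))
  edge2 <- t(sapply(rev(thetas), mk, z = L))
  side1 <- t(sapply(seq(0, L, length.out = 8)[-c(1, 8)], function(z) mk(half, z)))
  side2 <- t(sapply(seq(L, 0, length.out = 8)[-c(1, 8)], function(z) mk(-half, z)))
  rbind(edge1, side1, edge2, side2)
}

# full-enumeration two-sided Wilcoxon rank-sum oracle (small n, no ties)
wilcoxonEnumOracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  mu <- n * (length(y)) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

randomHeartGeometry <- function() {
  rt <- runif(1, 30, 70)
  Rb <- rt + runif(1, 40, 120)
  heartModel(sample(c("36", "48"), 1), bendRadius = Rb, tubeRadius = rt,
             bendAngle = runif(1, 0.8, 1.9),
             cellDiameterTypical = runif(1, 5, 14))
}
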