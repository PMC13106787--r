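# SuperPlot summaries, Wilcoxon comparisons, star labels and
# cross-experiment normalization.

test_that("superplot summaries compute embryo means and grand means", {
  df <- data.frame(cell_id = paste0("c", 1:6),
                   embryo_id = c("e1", "e1", "e1", "e2", "e2", "e3"),
                   region = "OC",
                   val = c(1, 2, 3, 1, 3, 5), stringsAsFactors = FALSE)
  sp <- superplotSummarize(df[1:3, ], "region", "val")
  expect_equal(sp$embryoMeans$embryo_mean, 2)
  sp2 <- superplotSummarize(df[c(1, 4, 5, 6), ], "region", "val")
  # embryos: e1 -> 1, e2 -> 2, e3 -> 5; grand mean of embryo means
  expect_equal(sort(sp2$embryoMeans$embryo_mean), c(1, 2, 5))
  expect_equal(sp2$groups$grand_mean, mean(c(1, 2, 5)))
  expect_identical(sp2$groups$n_cells, 4L)
  expect_identical(sp2$groups$N_embryos, 3L)
  # permutation invariance
  shuf <- df[sample(nrow(df)), ]
  spA <- superplotSummarize(df, "region", "val")
  spB <- superplotSummarize(shuf, "region", "val")
  expect_equal(spA$groups, spB$groups)
  expect_equal(spA$embryoMeans, spB$embryoMeans, ignore_attr = TRUE)
  dfBad <- df; dfBad$embryo_id[2] <- NA
  expect_error(superplotSummarize(dfBad, "region", "val"), "embryo_id")
})

test_that("superplot figures can be built", {
  df <- data.frame(cell_id = paste0("c", 1:8),
                   embryo_id = rep(c("e1", "e2"), each = 4),
                   region = rep(c("OC", "IC"), 4),
                   val = rnorm(8, 10), stringsAsFactors = FALSE)
  p <- plotSuperplot(superplotSummarize(df, "region", "val"))
  expect_s3_class(p, "ggplot")
})

test_that("wilcoxon comparison matches exact enumeration for small samples", {
  r <- wilcoxonCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  r2 <- wilcoxonCompare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$p_value, 0.1)  # 2 of C(6,3) = 20 labelings as extreme
  expect_identical(r2$stars, "ns")
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    x <- sample(seq_len(50), n); y <- sample(seq_len(50) + 100, m)
    pool <- sample(c(x, y))  # mix so groups interleave
    x <- pool[seq_len(n)]; y <- pool[-seq_len(n)]
    expect_equal(wilcoxonCompare(x, y)$p_value, wilcoxonEnumOracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxonCompare(numeric(0), 1:3), "non-empty")
})

test_that("wilcoxon rejects strongly separated groups at cohort-scale n", {
  set.seed(77)
  rejections <- vapply(1:500, function(i) {
    x <- rnorm(200, 0, 1); y <- rnorm(200, 1, 1)
    wilcoxonCompare(x, y)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.99)
})

test_that("star labels are a pure threshold function of p", {
  expect_identical(starLabel(c(0.2, 0.04, 0.009, 0.0009)),
                   c("ns", "*", "**", "***"))
  set.seed(8)
  p <- runif(1000)^3
  expected <- ifelse(p < 0.001, "***",
                     ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
  expect_identical(starLabel(p), expected)
})

test_that("cross-experiment normalization reproduces hand arithmetic", {
  # ctrl mean 12, SD 2; exp z-scores {-2, -1}; reference (100, 10) -> 85
  r <- crossExperimentNormalize(c(8, 10), c(10, 12, 14), 100, 10)
  expect_equal(r$mean_z, -1.5)
  expect_equal(r$mean_norm, 85)
  # mean_z = 0 -> the reference mean itself
  r0 <- crossExperimentNormalize(c(11, 13), c(10, 12, 14), 100, 10)
  expect_equal(r0$mean_norm, 100)
  expect_error(crossExperimentNormalize(c(1, 2), c(5, 5, 5), 100, 10), "SD")
  expect_error(crossExperimentNormalize(numeric(0), c(1, 2), 100, 10), "empty")
  # affine equivariance: shifting/scaling exp and ctrl together changes nothing
  set.seed(10)
  for (i in 1:20) {
    ctrl <- rnorm(15, 50, 7); exp <- rnorm(10, 42, 6)
    a <- runif(1, 0.5, 3); bshift <- rnorm(1, 0, 20)
    r1 <- crossExperimentNormalize(exp, ctrl, 142, 43)
    r2 <- crossExperimentNormalize(a * exp + bshift, a * ctrl + bshift, 142, 43)
    expect_equal(r2$mean_z, r1$mean_z, tolerance = 1e-9)
    expect_equal(r2$mean_norm, r1$mean_norm, tolerance = 1e-9)
  }
  # the group-mean shortcut is algebraically identical for mean_z
  ctrl <- c(10, 12, 14); exp <- c(8, 10)
  expect_equal(crossExperimentNormalize(exp, ctrl, 100, 10)$mean_z,
               (mean(exp) - mean(ctrl)) / sd(ctrl))
})

test_that("OC/IC populations separate significantly at cohort-scale n", {
  cfg <- generatorConfig()
  set.seed(31)
  hitsArea <- logical(100); hitsLen <- logical(100)
  for (i in 1:100) {
    ocA <- sampleTruncNormStratified(55, cfg@areaMean[["OC"]], cfg@areaSD[["OC"]])
    icA <- sampleTruncNormStratified(28, cfg@areaMean[["IC"]], cfg@areaSD[["IC"]])
    ocL <- sampleTruncNormStratified(55, cfg@heightMean[["OC"]], cfg@heightSD[["OC"]])
    icL <- sampleTruncNormStratified(28, cfg@heightMean[["IC"]], cfg@heightSD[["IC"]])
    hitsArea[i] <- wilcoxonCompare(ocA, icA)$p_value < 0.05
    hitsLen[i] <- wilcoxonCompare(ocL, icL)$p_value < 0.05
  }
  expect_gte(mean(hitsArea), 0.95)
  expect_gte(mean(hitsLen), 0.95)
  # and the qualitative ordering is as expected: OC larger, IC taller
  expect_gt(cfg@areaMean[["OC"]], cfg@areaMean[["IC"]])
  expect_gt(cfg@heightMean[["IC"]], cfg@heightMean[["OC"]])
})
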