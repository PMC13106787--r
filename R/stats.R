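# Statistical reporting layer: SuperPlot-style hierarchical summaries,
# two-sided Wilcoxon rank-sum comparisons with star labels, and the
# cross-experiment Z-score normalization of group means.

#' SuperPlot-style hierarchical summary
#'
#' Retains cell-level values, adds per-embryo means (the large dots of a
#' SuperPlot) and a per-group grand mean of embryo means, and reports
#' "N embryos, n cells" per group.
#'
#' @param records data.frame with at least cell_id, embryo_id, the grouping
#'   column(s) and the metric column.
#' @param groupBy name(s) of the grouping column(s).
#' @param metric name of the value column.
#' @return list of class "SuperPlotTable": \code{cells} (long rows),
#'   \code{embryoMeans}, \code{groups} (grand mean, n cells, N embryos).
#' @export
superplotSummarize <- function(records, groupBy, metric) {
  need <- c("cell_id", "embryo_id", groupBy, metric)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(records$embryo_id)) || any(records$embryo_id == ""))
    stop("records with missing embryo_id")
  grp <- interaction(records[groupBy], drop = TRUE, sep = "/")
  cells <- data.frame(cell_id = records$cell_id,
                      embryo_id = records$embryo_id,
                      group = as.character(grp),
                      value = records[[metric]], stringsAsFactors = FALSE)
  em <- stats::aggregate(value ~ group + embryo_id, data = cells, FUN = mean)
  names(em)[names(em) == "value"] <- "embryo_mean"
  gs <- stats::aggregate(embryo_mean ~ group, data = em, FUN = mean)
  names(gs)[names(gs) == "embryo_mean"] <- "grand_mean"
  gs$n_cells <- as.integer(table(cells$group)[gs$group])
  gs$N_embryos <- as.integer(table(em$group)[gs$group])
  structure(list(metric = metric, cells = cells,
                 embryoMeans = em[order(em$group, em$embryo_id), ],
                 groups = gs),
            class = "SuperPlotTable")
}

#' @export
print.SuperPlotTable <- function(x, ...) {
  cat(sprintf("SuperPlotTable for '%s'\n", x$metric))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: grand mean %.3f (N = %d embryos, n = %d cells)\n",
                x$groups$group[i], x$groups$grand_mean[i],
                x$groups$N_embryos[i], x$groups$n_cells[i]))
  invisible(x)
}

#' Star label for a p-value
#'
#' "***" for p < 0.001, "**" for p < 0.01, "*" for p < 0.05, otherwise "ns".
#'
#' @param p p-value(s).
#' @return character vector of labels.
#' @export
starLabel <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact p-values for small untied samples, normal approximation with
#' mid-ranks and tie-corrected variance otherwise (the default behaviour of
#' \code{stats::wilcox.test}). Comparisons run at cell level by default,
#' matching how group sizes are reported in figure legends; an embryo-level
#' comparison can be made by passing per-embryo means.
#'
#' @param groupA,groupB numeric value vectors.
#' @param labelA,labelB group names for the report.
#' @return data.frame: group_a, group_b, statistic, p_value, stars, n_a, n_b.
#' @export
wilcoxonCompare <- function(groupA, groupB, labelA = "A", labelB = "B") {
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(groupA, groupB,
                                            alternative = "two.sided"))
  data.frame(group_a = labelA, group_b = labelB,
             statistic = unname(wt$statistic), p_value = wt$p.value,
             stars = starLabel(wt$p.value),
             n_a = length(groupA), n_b = length(groupB),
             stringsAsFactors = FALSE)
}

#' Cross-experiment normalization of a group mean onto a reference scale
#'
#' Each experimental value is Z-scored against the within-experiment control
#' group (control mean, control sample SD with n-1 denominator); the group's
#' mean Z-score is then mapped onto the reference dataset's scale:
#' mean_norm = mean_ref + SD_ref * mean(Z). With the reported 48 hpf
#' wild-type OC apical-area reference (mean 142 um^2, SD 43 um^2) and a mean
#' Z of -0.67 this yields 113 um^2 (nearest integer).
#'
#' @param expValues experimental group's per-cell values.
#' @param ctrlValues within-experiment control group's per-cell values.
#' @param meanRef,sdRef reference dataset mean and SD.
#' @param metric optional metric name for the report.
#' @return data.frame: metric, mean_ref, sd_ref, mean_ctrl, sd_ctrl, mean_z,
#'   mean_norm, mean_norm_rounded.
#' @export
crossExperimentNormalize <- function(expValues, ctrlValues, meanRef, sdRef,
                                     metric = NA_character_) {
  if (length(expValues) == 0) stop("empty experimental group")
  if (length(ctrlValues) < 2) stop("control group needs at least 2 values")
  mCtrl <- mean(ctrlValues)
  sCtrl <- stats::sd(ctrlValues)
  if (sCtrl == 0) stop("control SD is zero; Z-scores undefined")
  if (sdRef < 0) stop("reference SD must be >= 0")
  z <- (expValues - mCtrl) / sCtrl
  meanZ <- mean(z)
  res <- normalizeGroupMean(meanRef, sdRef, meanZ)
  data.frame(metric = metric, mean_ref = meanRef, sd_ref = sdRef,
             mean_ctrl = mCtrl, sd_ctrl = sCtrl, mean_z = meanZ,
             mean_norm = res, mean_norm_rounded = round(res),
             stringsAsFactors = FALSE)
}

#' Map a mean Z-score onto a reference scale
#'
#' mean_norm = mean_ref + SD_ref * mean_z.
#'
#' @param meanRef,sdRef reference dataset mean and SD.
#' @param meanZ mean Z-score of the experimental group.
#' @return mean_norm, in reference units.
#' @export
normalizeGroupMean <- function(meanRef, sdRef, meanZ) {
  if (!all(is.finite(c(meanRef, sdRef, meanZ)))) stop("non-finite inputs")
  meanRef + sdRef * meanZ
}
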