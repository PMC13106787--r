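# SuperPlot figure: cell-level points with per-embryo means superimposed.

#' SuperPlot of a metric by group
#'
#' Cell-level values are drawn as small jittered points, per-embryo means as
#' large dots coloured by embryo, and the group grand mean (of embryo means)
#' as a crossbar. Counts are reported in the subtitle as "N embryos, n
#' cells" per group.
#'
#' @param sp a SuperPlotTable from \code{\link{superplotSummarize}}.
#' @param ylab y-axis label; defaults to the metric name.
#' @return a ggplot object.
#' @export
plotSuperplot <- function(sp, ylab = sp$metric) {
  stopifnot(inherits(sp, "SuperPlotTable"))
  counts <- sprintf("%s: N = %d embryos, n = %d cells", sp$groups$group,
                    sp$groups$N_embryos, sp$groups$n_cells)
  ggplot2::ggplot(sp$cells, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_jitter(width = 0.18, height = 0, size = 0.8,
                         colour = "grey55", alpha = 0.7) +
    ggplot2::geom_point(data = sp$embryoMeans,
                        ggplot2::aes(y = embryo_mean, colour = embryo_id),
                        size = 3.2) +
    ggplot2::stat_summary(data = sp$embryoMeans,
                          ggplot2::aes(y = embryo_mean),
                          fun = mean, geom = "crossbar",
                          width = 0.45, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = ylab, colour = "embryo",
                  subtitle = paste(counts, collapse = "; ")) +
    ggplot2::theme_classic()
}
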