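#' Mean perceived heading against actual heading
#'
#' One point per (condition, actual heading): grand mean perceived heading
#' across participants with between-participant SE bars. The dashed diagonal
#' marks veridical performance; the dashed horizontal at 0 deg marks pure
#' center bias (always reporting straight ahead).
#'
#' @param table a response table.
#' @return A ggplot object; its `$data` holds the plotted summary.
#' @export
plot_ph_by_ah <- function(table) {
  pm <- stats::aggregate(ph_deg ~ participant + condition + ah_deg, table,
                         mean)
  agg <- stats::aggregate(ph_deg ~ condition + ah_deg, pm, function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  })
  summ <- data.frame(condition = agg$condition, ah_deg = agg$ah_deg,
                     mean_ph = agg$ph_deg[, "mean"], se = agg$ph_deg[, "se"])
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$ah_deg, y = .data$mean_ph,
                                     colour = .data$condition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ph - .data$se,
                                        ymax = .data$mean_ph + .data$se),
                           width = 1.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "actual heading (deg)",
                  y = "perceived heading (deg)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Residual heading error against relative heading
#'
#' Binned means of the residual heading error (RHE) over the relative
#' heading (previous minus current actual heading) with the pooled fitted
#' line. A negative slope indicates repulsion from the previous heading.
#'
#' @param sd_result a [serial_dependence()] result.
#' @param bin_width bin width in degrees for the displayed means.
#' @return A ggplot object; its `$data` holds the binned summary.
#' @export
plot_serial_dependence <- function(sd_result, bin_width = 6) {
  stopifnot(inherits(sd_result, "serial_dependence_result"))
  tr <- sd_result$trials
  bin <- bin_width * round(tr$rh / bin_width)
  agg <- stats::aggregate(tr$rhe, list(rh_bin = bin), function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  summ <- data.frame(rh_bin = agg$rh_bin, mean_rhe = agg$x[, "mean"],
                     se = agg$x[, "se"], n_trials = agg$x[, "n"])
  # pooled intercept of the stage-2 fit, for the drawn line
  stats_mat <- .serial_stats(tr)
  s <- colSums(stats_mat)
  slope <- sd_result$sd_slope
  intercept <- (s[["sy"]] - slope * s[["sx"]]) / s[["n"]]
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$rh_bin, y = .data$mean_rhe)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rhe - .data$se,
                                        ymax = .data$mean_rhe + .data$se),
                           width = 1.5, colour = "grey30") +
    ggplot2::geom_point(size = 2, colour = "grey30") +
    ggplot2::geom_abline(slope = slope, intercept = intercept,
                         colour = "red") +
    ggplot2::labs(
      x = "relative heading: previous - current (deg)",
      y = "residual heading error (deg)",
      title = sprintf("%s: s' = %.4f", sd_result$condition, slope)) +
    ggplot2::theme_minimal()
}
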