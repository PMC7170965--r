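# ggplot2 visualizations for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a saturation, recurrence or coverage-saturation curve
#'
#' @param object A `saturation_curve` tibble from
#'   [replicate_saturation()], [recurrence_curve()] or
#'   [coverage_saturation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saturation_curve <- function(object, ...) {
  metric <- attr(object, "metric")
  if (identical(metric, "replicate_saturation")) {
    ggplot2::ggplot(object, ggplot2::aes(factor(.data$k), .data$n_peaks)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
      ggplot2::labs(x = "replicates", y = "peaks captured")
  } else if (identical(metric, "recurrence")) {
    ggplot2::ggplot(object, ggplot2::aes(.data$r, .data$percent)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "detected in at least r replicates",
                    y = "% of union peaks")
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(.data$bin_lo, .data$percent,
                                 colour = factor(.data$threshold))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "mean input coverage (X)",
                    y = "% of genes with >= k peaks", colour = "k")
  }
}

#' Fold-change decomposition plot of a differential-methylation fit
#'
#' Peak-IP versus gene-input log2 fold changes; points on the diagonal
#' change proportionally with gene expression (no methylation change),
#' points off the diagonal by at least the delta threshold are candidate
#' differential methylation.
#'
#' @param object A `merip_diffmeth` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.merip_diffmeth <- function(object, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(.data$gene_input_log2fc,
                               .data$peak_ip_log2fc,
                               colour = .data$passes_filters)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "gene input log2FC", y = "peak IP log2FC",
                  colour = "passes filters")
}

#' Histogram of bootstrap mean log-likelihoods
#'
#' @param object A `fit_report` from [bootstrap_loglik_percentile()]; the
#'   observed mean log-likelihood is drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fit_report <- function(object, ...) {
  df <- tibble::tibble(loglik = object$simulated_mean_logliks)
  ggplot2::ggplot(df, ggplot2::aes(.data$loglik)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed_mean_loglik,
                        colour = "red") +
    ggplot2::labs(x = "simulated mean log-likelihood",
                  title = paste0(object$model, " (percentile ",
                                 round(object$percentile_of_observed, 1),
                                 ")"))
}

#' Plot p-value histograms per dispersion variant
#'
#' A well-calibrated test gives a flat histogram on null data.
#'
#' @param fit A `merip_diffmeth` object.
#' @return A ggplot object.
#' @export
plot_pvalue_histogram <- function(fit) {
  df <- dplyr::bind_rows(lapply(names(fit$results), function(v) {
    tibble::tibble(variant = v, p_value = fit$results[[v]]$p_value)
  }))
  ggplot2::ggplot(df[!is.na(df$p_value), ], ggplot2::aes(.data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05),
                            boundary = 0, closed = "left") +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "unadjusted p-value", y = "peaks")
}

#' Mean +/- SD coverage plot for one gene
#'
#' Lines show the mean coverage across replicates; shading shows the
#' standard deviation, split by fraction and condition.
#'
#' @param summary Output of [coverage_summary()].
#' @param gene Gene id to plot.
#' @param free_y Scale the y axis separately per condition.
#' @return A ggplot object.
#' @export
plot_coverage <- function(summary, gene, free_y = FALSE) {
  df <- summary[summary$gene_id == gene, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$mean_depth,
                                   colour = .data$fraction,
                                   fill = .data$fraction)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_depth - .data$sd_depth, 0),
      ymax = .data$mean_depth + .data$sd_depth),
      alpha = 0.3, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition, ncol = 1,
                        scales = if (free_y) "free_y" else "fixed") +
    ggplot2::labs(x = "position in gene (bp)", y = "coverage",
                  title = gene)
}

#' Power curves from replicate subsampling
#'
#' @param object A `power_curve` tibble from [subsample_power()].
#' @param ... Unused.
#' @return A ggplot object: mean detection fraction versus replicates,
#'   with the per-peak curves underlaid.
#' @export
autoplot.power_curve <- function(object, ...) {
  avg <- object |>
    dplyr::summarise(fraction_detected = mean(.data$fraction_detected),
                     .by = "k")
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$fraction_detected)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$peak_id), alpha = 0.2) +
    ggplot2::geom_line(data = avg, colour = "red", linewidth = 1.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "replicates per condition",
                  y = "fraction of subsamples detected")
}
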