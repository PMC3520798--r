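#' Plot pooled analyte effects
#'
#' Forest-style display of the pooled Cliff's deltas: analytes ordered
#' by effect, point estimates with confidence intervals, coloured by
#' significance.
#'
#' @param object A `pooled_effects` table from [run_meta()].
#' @param n_top Show only the `n_top` smallest-q analytes (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pooled_effects
#' @export
autoplot.pooled_effects <- function(object, n_top = 40, ...) {
  df <- as_tibble(object) %>%
    filter(!.data$excluded) %>%
    arrange(.data$q) %>%
    head(n_top) %>%
    mutate(analyte = stats::reorder(.data$analyte, .data$delta_pooled))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_pooled,
                                   y = .data$analyte,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B",
                                            `FALSE` = "grey55")) +
    ggplot2::labs(x = "pooled Cliff's delta (male - female)",
                  y = NULL, colour = "q < alpha") +
    ggplot2::theme_minimal()
}

#' Plot composite cluster sex differences
#'
#' Forest plot of the pooled male-minus-female composite difference per
#' analyte cluster with 95% confidence bars, the cluster-level analogue
#' of the per-analyte forest.
#'
#' @param object A `composite_results` from [composite_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composite_results
#' @export
autoplot.composite_results <- function(object, ...) {
  df <- object$clusters %>%
    mutate(cluster = factor(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_pooled,
                                   y = .data$cluster)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "pooled composite difference (male - female)",
                  y = "analyte cluster") +
    ggplot2::theme_minimal()
}

#' Plot the analyte map of a cluster model
#'
#' Analytes as observations over the reference cohort's samples,
#' projected on the first two principal components and coloured by
#' cluster; optionally sized/shaped by meta-analysis significance when a
#' pooled table is supplied.
#'
#' @param object A `cluster_model` from [cluster_analytes()].
#' @param pooled Optional `pooled_effects` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_model
#' @export
autoplot.cluster_model <- function(object, pooled = NULL, ...) {
  df <- analyte_map(object, pooled)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                        colour = factor(.data$cluster)))
  if (!is.null(pooled)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$significant))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "PC1", y = "PC2", colour = "cluster") +
    ggplot2::theme_minimal()
}
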