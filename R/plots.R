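#' Trace plots for a posterior sample
#'
#' @param object a `mosaic_posterior`.
#' @param ... unused.
#' @return a ggplot (tree height and gamma shape against state).
#' @export
autoplot.mosaic_posterior <- function(object, ...) {
  d <- tidyr::pivot_longer(object$trace,
                           c("treeHeight", "gammaShape"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "MCMC state", y = NULL) +
    ggplot2::theme_minimal()
}

#' Observed-vs-predicted plot for a fitted regression
#'
#' @param object a `mosaic_ols`.
#' @param labels optional point labels (e.g. subset names).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mosaic_ols <- function(object, labels = NULL, ...) {
  d <- tibble(observed = object$lm$model$.y,
              predicted = stats::fitted(object$lm))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = mean(d$observed), colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s predicted", object$response),
      y = sprintf("%s observed", object$response),
      subtitle = sprintf("R² = %.2f, F = %.1f (p = %.2g), n = %d",
                         object$r_squared, object$f_ratio, object$f_p,
                         object$n_obs)) +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    d$label <- labels
    p <- p + ggplot2::geom_text(data = d,
                                ggplot2::aes(label = .data$label),
                                nudge_y = diff(range(d$observed)) / 30,
                                size = 3)
  }
  p
}

#' Partition separation in metric space
#'
#' Scatter of tree height against log shape, point size showing mean clade
#' support: the planar view of the three-metric space in which a mosaic
#' partition separates from the rest.
#'
#' @param design design-matrix tibble with `TreeHeight`, `Shape` and a
#'   support column.
#' @param support_col support column name (default `S_WAG`).
#' @return a ggplot.
#' @export
plot_metric_space <- function(design, support_col = "S_WAG") {
  ggplot2::ggplot(design,
                  ggplot2::aes(x = .data$TreeHeight, y = log(.data$Shape),
                               size = .data[[support_col]],
                               label = .data$Subset)) +
    ggplot2::geom_point(alpha = 0.7, colour = "firebrick") +
    ggplot2::geom_text(size = 3, nudge_y = 0.08, show.legend = FALSE) +
    ggplot2::labs(x = "Tree height", y = "log(shape)",
                  size = "mean support S") +
    ggplot2::theme_minimal()
}

#' Per-clade support barplot
#'
#' @param support tibble from [clade_support()] (optionally several,
#'   row-bound with a `partition` column).
#' @return a ggplot.
#' @export
plot_clade_support <- function(support) {
  p <- ggplot2::ggplot(support,
                       ggplot2::aes(x = .data$clade, y = .data$support)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = expression(S[i])) +
    ggplot2::theme_minimal()
  if ("partition" %in% names(support)) {
    p <- p + ggplot2::facet_wrap(~partition)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
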