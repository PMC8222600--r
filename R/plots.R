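# ggplot2 views of the pipeline's result tables.

#' Plot a coverage/overlap report
#'
#' Bar panels of per-source coverage and overlap across section kinds,
#' mirroring the layout of the integration summary table.
#'
#' @param object A `coverage_report` from [coverage_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("coverage", "overlap"),
    names_to = "measure", values_to = "percent"
  )
  long <- dplyr::filter(long, !is.na(.data$percent))
  long$section <- factor(long$section, levels = rev(unique(object$section)))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$percent, y = .data$section, fill = .data$source)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(
      x = "percent of applications", y = NULL, fill = "source",
      title = "Per-source coverage and overlap of labeling sections"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a learning curve
#'
#' Mean test F1 against training-set size, one line per algorithm.
#'
#' @param object A `fe_learning_curve` from [learning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fe_learning_curve
#' @export
autoplot.fe_learning_curve <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$size, y = .data$mean_f1,
      colour = .data$algo, group = .data$algo
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "training examples", y = "mean test F1", colour = "algorithm",
      title = "Learning curve of food-effect paragraph classification"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a method-comparison report
#'
#' Dot plot of precision, recall and F1 for each evaluated method
#' (rule-based baselines and TF-IDF classifiers).
#'
#' @param methods Output of [eval_methods()].
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(methods) {
  long <- tidyr::pivot_longer(methods, c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  long$method <- factor(long$method, levels = rev(unique(methods$method)))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$value, y = .data$method, colour = .data$metric)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      x = NULL, y = NULL, colour = NULL,
      title = "Food-effect labeling: rule-based vs TF-IDF classifiers"
    ) +
    ggplot2::theme_minimal()
}
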