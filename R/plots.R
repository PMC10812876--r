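# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_abline geom_violin
#'   geom_col geom_line geom_point facet_wrap labs theme_minimal coord_flip
NULL

#' Plot an ROC curve
#'
#' @param object An `oudel_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oudel_roc <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))) +
    theme_minimal()
}

#' Violin plot of signed parameter-prediction errors
#'
#' @param errors Tibble from [error_distributions()].
#' @return A ggplot faceted by output kind, split by class when available.
#' @export
plot_error_distributions <- function(errors) {
  p <- ggplot(errors, aes(x = .data$output, y = .data$error))
  if ("class" %in% names(errors)) {
    p <- p + geom_violin(aes(fill = .data$class), position = "dodge")
  } else {
    p <- p + geom_violin(fill = "grey80")
  }
  p + labs(x = NULL, y = "Predicted - true") + theme_minimal()
}

#' Bar chart of Shapley feature importance
#'
#' @param importance Tibble from [shapley_importance()].
#' @return A ggplot of mean absolute Shapley value per feature, coloured by
#'   gene role.
#' @export
plot_shapley_importance <- function(importance) {
  imp <- dplyr::mutate(importance,
                       feature = factor(.data$feature,
                                        levels = rev(importance$feature)))
  ggplot(imp, aes(x = .data$feature, y = .data$mean_abs_shapley,
                  fill = .data$role)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Mean |Shapley value|") +
    theme_minimal()
}

#' Power/accuracy across noise levels
#'
#' @param noise Tibble from [noise_experiment()].
#' @param metric Column to plot.
#' @return A ggplot, one line per architecture over log10 noise sd.
#' @export
plot_noise_experiment <- function(noise, metric = "power") {
  ggplot(noise, aes(x = log10(.data$noise_sd), y = .data[[metric]],
                    colour = .data$architecture)) +
    geom_line() +
    geom_point() +
    labs(x = "log10 noise sd", y = metric) +
    theme_minimal()
}
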