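#' ROC curve of a cross-validation result
#'
#' Plots the pooled out-of-fold ROC with the chance diagonal and the mean
#' AUROC in the subtitle.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Pooled cross-validated ROC",
                  subtitle = sprintf("mean AUROC = %.3f over %d folds",
                                     object$mean_auroc, object$n_folds)) +
    ggplot2::theme_minimal()
}

#' Training-objective trace of a skip-gram model
#'
#' @param object An `msg_model`.
#' @param ... Unused.
#' @return A ggplot object showing the mean hierarchical-softmax
#'   log-likelihood after each epoch.
#' @export
autoplot.msg_model <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$objective),
                       mean_loglik = object$objective)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mean_loglik)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Epoch", y = "Mean HS log-likelihood",
                  title = "Skip-gram training objective") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-class enrichment accuracy
#'
#' @param accuracy The tibble returned by [accuracy_table()] or
#'   [accuracy_from_counts()].
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy) {
  df <- accuracy %>%
    dplyr::mutate(class_name = factor(.data$class_name,
                                      levels = accuracy$class_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_name, y = .data$accuracy,
                                   fill = .data$class_name == "Total")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$accuracy)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_fill_manual(values = c("FALSE" = "#2c7fb8",
                                          "TRUE" = "#636363")) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = NULL, y = "Enrichment accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
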