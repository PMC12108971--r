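# ggplot2 displays for fitted models, leave-one-out runs and comparisons.

#' Plot the training-loss history of a fitted network
#'
#' @param object A `tsfnn_model`.
#' @param ... Unused.
#' @return A ggplot: mean training binary cross-entropy per epoch.
#' @method autoplot tsfnn_model
#' @export
autoplot.tsfnn_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Epoch", y = "Training loss (binary cross-entropy)",
      title = sprintf("Training history (%s)", object$spec$architecture)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold probabilities of a leave-one-out run
#'
#' Each point is one held-out record's predicted fracture probability,
#' coloured by its true class, with the decision threshold drawn as a
#' horizontal line. Separation of the two colour bands across the line is
#' what the pooled metrics summarize.
#'
#' @param object A `loocv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loocv_result
#' @export
autoplot.loocv_result <- function(object, ...) {
  folds <- dplyr::mutate(
    object$folds,
    class = factor(ifelse(.data$truth == 1, "fractured", "nonfractured"),
                   levels = c("nonfractured", "fractured"))
  )
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$fold, y = .data$prob,
                                      colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$spec$decision_threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(nonfractured = "#1b9e77", fractured = "#d95f02")
    ) +
    ggplot2::labs(
      x = "Held-out record (fold index)", y = "Predicted fracture probability",
      colour = "True class",
      title = sprintf("Leave-one-out predictions (%s)", object$spec$architecture)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an architecture comparison
#'
#' Grouped bars of the four pooled leave-one-out metrics per model
#' (improvement rows are omitted from the plot).
#'
#' @param object A `model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  long <- as_tibble(object) %>%
    filter(.data$row == "model") %>%
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") %>%
    mutate(metric = factor(.data$metric,
                           levels = c("accuracy", "precision", "recall", "f1")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Pooled leave-one-out metric", fill = NULL,
                  title = "Architecture comparison") +
    ggplot2::theme_minimal()
}
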