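# ggplot2 displays for decode results, evaluation reports and importance
# tables.

#' @export
autoplot.hhmm_decode <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = posterior_hypnosis,
                                    color = "filtered posterior")) +
    ggplot2::geom_step(ggplot2::aes(
      y = as.numeric(viterbi_state == "hypnosis"),
      color = "Viterbi state"), alpha = 0.7) +
    ggplot2::labs(x = "time (s)", y = "P(hypnosis)", color = NULL,
                  title = "Decoded road-hypnosis state") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if ("label" %in% names(df)) {
    p <- p + ggplot2::geom_step(
      ggplot2::aes(y = as.numeric(label == "hypnosis"),
                   color = "true state"),
      linetype = 2, alpha = 0.6)
  }
  p
}

#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(fold), y = accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = 2) +
    ggplot2::labs(x = "fold", y = "row accuracy",
                  title = sprintf("%d-fold grouped CV (mean %.3f)",
                                  object$k, object$mean_accuracy)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.importance_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c(gain, cover, frequency),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = value,
                               y = stats::reorder(feature, value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Split-based feature importance") +
    ggplot2::theme_minimal()
}
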