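# ggplot2 displays for diagnoses and evaluations.

#' Plot the posterior-mean trajectory of a diagnosed nodule
#'
#' Shows the per-interval posterior mean of the malignancy score with the
#' class boundaries at 0.51 and 0.70.
#'
#' @param object A [run_filter()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nodule_diagnosis
#' @export
autoplot.nodule_diagnosis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$pme)) +
    ggplot2::geom_hline(yintercept = c(0.51, 0.70), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 2, colour = "#2c7fb8") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "screening interval",
      y = "posterior mean malignancy score",
      title = if (!is.na(object$nodule_id)) object$nodule_id else NULL,
      subtitle = sprintf("final %.3f (%s)", object$final_score,
                         as.character(object$label))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation's confusion matrix as a heatmap
#'
#' @param object A [evaluate_cohort()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_evaluation
#' @export
autoplot.cohort_evaluation <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::scale_y_discrete(limits = rev(class_levels())) +
    ggplot2::labs(x = "predicted", y = "truth",
                  subtitle = sprintf("accuracy %.3f, MCC %.3f",
                                     object$accuracy, object$mcc)) +
    ggplot2::theme_minimal()
}

#' Plot final diagnostic scores of a cohort by true class
#'
#' @param results A [run_cohort()] results tibble.
#' @param truth Truth tibble with `nodule_id` and `truth_label`.
#' @return A ggplot object.
#' @export
plot_cohort_scores <- function(results, truth) {
  joined <- dplyr::inner_join(tibble::as_tibble(results),
                              tibble::as_tibble(truth),
                              by = "nodule_id")
  ggplot2::ggplot(joined,
                  ggplot2::aes(x = .data$truth_label, y = .data$final_score,
                               colour = .data$truth_label)) +
    ggplot2::geom_hline(yintercept = c(0.51, 0.70), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "true class", y = "final posterior mean score") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
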