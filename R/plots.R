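#' Plot test accuracy across the evaluation design
#'
#' One point per condition and algorithm, faceted by stage, with the
#' majority-class baseline drawn as a dashed line; models below the line are
#' unsatisfactory screens.
#'
#' @param object An `iaq_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.iaq_evaluation <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$condition,
                               y = .data$test_accuracy,
                               colour = .data$algorithm)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline),
                       colour = "grey30", linetype = "dashed") +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "evaluation condition", y = "test accuracy",
                  colour = NULL,
                  title = "Classifier accuracy across the evaluation design",
                  subtitle = "dashed line: majority-class baseline") +
    ggplot2::theme_minimal()
}

#' Plot predicted satisfaction by IAQ-index bin
#'
#' Stacked per-bin percentages of predicted satisfactory and unsatisfactory
#' IAQ over the Monte-Carlo sample, one panel per scheme: the screening
#' picture behind the likelihood-ratio update.
#'
#' @param object An `iaq_screening_update`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.iaq_screening_update <- function(object, ...) {
  d <- tidyr::pivot_longer(object$percentages,
                           c("pct_satisfactory", "pct_unsatisfactory"),
                           names_to = "outcome", values_to = "pct",
                           names_prefix = "pct_")
  d$bin <- factor(d$bin, levels = object$bins$bin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$pct,
                                  fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = "IAQ index bin", y = "predicted %", fill = NULL,
                  title = "Model-averaged IAQ prediction by index bin") +
    ggplot2::theme_minimal()
}

#' Histogram of the IAQ index by assessment group
#'
#' @param data Office records (labelled, or labelled on the fly with
#'   `scheme`).
#' @param scheme Scheme used when no `label` column is present.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_index_distribution <- function(data, scheme = scheme_hk(1), bins = 40) {
  if (!"label" %in% names(data)) data <- assess_iaq(data, scheme)
  d <- iaq_index(data)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, fill = .data$label)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "IAQ index θ", y = "offices", fill = NULL,
                  title = "Surrogate IAQ index by assessment outcome") +
    ggplot2::theme_minimal()
}
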