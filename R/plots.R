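# ggplot2 display methods for fitted models and metric reports.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training loss curve
#'
#' @param object An `mvp_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mvp_model
#' @export
autoplot.mvp_model <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Epoch", y = "Mean contrastive loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Plot rank@k as a staircase
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  ggplot2::ggplot(object$rank_at,
                  ggplot2::aes(x = .data$k, y = .data$rank_at)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "k", y = "rank@k (%)",
                  title = "Retrieval performance") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
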