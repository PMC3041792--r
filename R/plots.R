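# --- ggplot2 visualisations ------------------------------------------------

#' Plot methods for gbabias result objects
#'
#' `autoplot()` gives each result type its standard display: per-group
#' metric histograms for evaluations, the degree-AUC versus predictor-AUC
#' scatter (with identity line) for bias reports, the empirical p-value
#' histogram for null results, the score decay for multifunctionality
#' scores, and the per-link similarity histogram for link similarity
#' results.
#'
#' @param object A gbabias result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gbabias-autoplot
NULL

#' @rdname gbabias-autoplot
#' @export
autoplot.gba_evaluation <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = 0.025, boundary = 0,
                            fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(
      x = sprintf("per-group %s (%s)", attr(object, "metric"),
                  attr(object, "predictor")),
      y = "groups"
    )
}

#' @rdname gbabias-autoplot
#' @export
autoplot.bias_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$degree_auc,
                               y = .data$predictor_auc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "node-degree ranking AUC",
                  y = sprintf("%s AUC", attr(object, "predictor")))
}

#' @rdname gbabias-autoplot
#' @export
autoplot.gba_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "grey35") +
    ggplot2::labs(x = "degree-corrected empirical p-value", y = "groups")
}

#' @rdname gbabias-autoplot
#' @export
autoplot.mf_scores <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- dplyr::arrange(d, dplyr::desc(.data$score))
  d$position <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gene rank", y = "multifunctionality score")
}

#' @rdname gbabias-autoplot
#' @export
autoplot.link_similarity <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$similarity)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "grey35") +
    ggplot2::geom_vline(xintercept = attr(object, "baseline_mean"),
                        linetype = 2) +
    ggplot2::labs(x = sprintf("per-link %s similarity",
                              attr(object, "measure")),
                  y = "links")
}
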