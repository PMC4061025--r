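#' Plot a background model fit
#'
#' Observed cumulative counts N(n) against the fitted geometric-plus-offset
#' curve, on a log10 count scale.
#'
#' @param object An `occupeak_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupeak_fit <- function(object, ...) {
  df <- object$counts
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$N), size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "overlap depth n",
      y = "regions with depth ≥ n",
      title = sprintf("Background fit: p = %.3g, A = %.3g bp, B = %.3g",
                      object$p, object$A, object$B)
    ) +
    ggplot2::theme_minimal()
}

#' Plot called peaks by significance
#'
#' Histogram of peak log10 excess ratios with the applied threshold marked.
#'
#' @param object An `occupeak_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupeak_calls <- function(object, ...) {
  ggplot2::ggplot(object$peaks, ggplot2::aes(x = .data$log_er)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "log10 excess ratio", y = "peaks",
                  title = sprintf("%d peaks at log10(ER) ≥ %.2f",
                                  nrow(object$peaks), object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a fragment-length estimate
#'
#' Histogram of the forward/reverse region midpoint distances with the
#' median (the estimate) marked.
#'
#' @param object A `fragment_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fragment_estimate <- function(object, ...) {
  df <- tibble::tibble(distance = object$distances)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$length, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "forward-to-reverse midpoint distance (bp)", y = "pairs",
                  title = sprintf("Fragment length estimate: %d bp", object$length)) +
    ggplot2::theme_minimal()
}
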