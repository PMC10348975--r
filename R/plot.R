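# ggplot2 visualizations for fitted objects.

#' Plot the estimated consciousness trace
#'
#' Time course of the ensemble-averaged consciousness level (0 = unconscious,
#' 1 = conscious), optionally with the per-method FCM and GMM traces.
#'
#' @param object A `consciousness_fit`.
#' @param show_methods Also draw the per-method traces (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consciousness_fit <- function(object, show_methods = TRUE, ...) {
  tr <- object$trace |>
    tidyr::pivot_longer(dplyr::all_of(c("p_fcm", "p_gmm", "p_conscious")),
                        names_to = "trace", values_to = "p")
  if (!show_methods) tr <- dplyr::filter(tr, .data$trace == "p_conscious")
  tr$trace <- factor(tr$trace, c("p_fcm", "p_gmm", "p_conscious"),
                     c("FCM", "GMM", "Ensemble"))
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_s, .data$p,
                                   colour = .data$trace,
                                   alpha = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::scale_alpha_manual(values = c(FCM = 0.4, GMM = 0.4, Ensemble = 1),
                                guide = "none") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "consciousness level", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of two features colored by conscious membership
#'
#' The soft-clustering view: each analysis window as a point in a feature
#' pair plane, colored by its degree of membership to the conscious cluster
#' (blue = unconscious, red = conscious).
#'
#' @param fit A `consciousness_fit`.
#' @param x_feature,y_feature Feature column names (normalized features).
#' @param method Which membership to color by: `"ensemble"` (default),
#'   `"fcm"`, or `"gmm"`.
#' @return A ggplot object.
#' @export
plot_feature_pair <- function(fit, x_feature = "sef95", y_feature = "lzc",
                              method = c("ensemble", "fcm", "gmm")) {
  stopifnot(inherits(fit, "consciousness_fit"))
  method <- match.arg(method)
  p <- switch(method, ensemble = fit$trace$p_conscious,
              fcm = fit$trace$p_fcm, gmm = fit$trace$p_gmm)
  df <- tibble::tibble(x = fit$features[[x_feature]],
                       y = fit$features[[y_feature]], p = p)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$p)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red", limits = c(0, 1)) +
    ggplot2::labs(x = x_feature, y = y_feature, colour = "P(conscious)") +
    ggplot2::theme_minimal()
}

#' Plot the accuracy-by-threshold sweep
#'
#' @param accuracy Tibble from [accuracy_vs_eyes()].
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy) {
  ggplot2::ggplot(accuracy, ggplot2::aes(.data$threshold, .data$accuracy)) +
    ggplot2::geom_col(width = 0.06, fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "binarization threshold", y = "accuracy vs eyes scoring") +
    ggplot2::theme_minimal()
}
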