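# ggplot2 visualizations for the main result types

#' @rdname physiocca_plots
#' @name physiocca_plots
#' @title Plot methods
#' @description `autoplot()` methods: lag-estimate cross-correlation
#'   profile, per-network ICC distributions, canonical score scatter and
#'   per-fold out-of-sample correlations.
#' @param object a physiocca result object.
#' @param ... unused.
#' @return A ggplot.
NULL

#' @rdname physiocca_plots
#' @export
autoplot.lag_estimate <- function(object, ...) {
  ggplot2::ggplot(object$xcorr_profile,
                  ggplot2::aes(x = .data$lag_s, y = .data$mean_r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lag_s, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "lag (s)", y = "mean cross-correlation",
                  title = sprintf("lag %+d frames (%.2f s), flip = %s",
                                  object$lag_frames, object$lag_s,
                                  object$flip)) +
    ggplot2::theme_minimal()
}

#' @rdname physiocca_plots
#' @export
autoplot.network_icc_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_roi,
                  ggplot2::aes(x = .data$network, y = .data$icc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "ICC",
                  subtitle = sprintf("Kruskal-Wallis H = %.2f, p = %.2g",
                                     object$kruskal_h, object$p_value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname physiocca_plots
#' @param mode mode index for the score scatter.
#' @export
autoplot.cca_fit <- function(object, mode = 1, ...) {
  d <- tibble::tibble(brain = object$xscores[, mode],
                      behavior = object$yscores[, mode])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$brain, y = .data$behavior)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "topographic score", y = "behavioral score",
                  title = sprintf("mode %d, canonical r = %.3f", mode,
                                  object$cor[mode])) +
    ggplot2::theme_minimal()
}

#' @rdname physiocca_plots
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$fold), y = .data$oos_r)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_oos_r, linetype = 2) +
    ggplot2::labs(x = "fold", y = "out-of-sample canonical r") +
    ggplot2::theme_minimal()
}
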