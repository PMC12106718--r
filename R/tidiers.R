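# broom-style tidiers for the fitted objects

#' @rdname physiocca_tidiers
#' @name physiocca_tidiers
#' @title Tidy and glance methods
#' @description Broom-style accessors: `tidy()` returns one row per
#'   element (lag, ROI, mode or fold), `glance()` a one-row model
#'   summary.
#' @param x a fitted physiocca object.
#' @param ... unused.
#' @return A tibble.
NULL

#' @rdname physiocca_tidiers
#' @export
tidy.lag_estimate <- function(x, ...) x$xcorr_profile

#' @rdname physiocca_tidiers
#' @export
glance.lag_estimate <- function(x, ...) {
  tibble::tibble(lag_frames = x$lag_frames, lag_s = x$lag_s,
                 flip = x$flip)
}

#' @rdname physiocca_tidiers
#' @export
tidy.topography <- function(x, ...) {
  tibble::tibble(roi = names(x$values), z = unname(x$values),
                 measure = x$measure)
}

#' @rdname physiocca_tidiers
#' @export
tidy.icc_map <- function(x, ...) x$table

#' @rdname physiocca_tidiers
#' @export
glance.icc_map <- function(x, ...) {
  tibble::tibble(variant = x$variant, n_participants = x$n_participants,
                 n_roi = nrow(x$table),
                 median_icc = median(x$table$icc, na.rm = TRUE),
                 mean_icc = mean(x$table$icc, na.rm = TRUE))
}

#' @rdname physiocca_tidiers
#' @export
tidy.cca_fit <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$cor), canonical_r = x$cor)
}

#' @rdname physiocca_tidiers
#' @export
glance.cca_fit <- function(x, ...) {
  tibble::tibble(n = x$n, k_x = x$k[["x"]], k_y = x$k[["y"]],
                 first_canonical_r = x$cor[1])
}

#' @rdname physiocca_tidiers
#' @export
tidy.cca_perm_test <- function(x, ...) x$table

#' @rdname physiocca_tidiers
#' @export
glance.cca_perm_test <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, alpha = x$alpha,
                 threshold_r = x$threshold,
                 n_significant = sum(x$table$significant))
}

#' @rdname physiocca_tidiers
#' @export
tidy.backprojection <- function(x, ...) x$table

#' @rdname physiocca_tidiers
#' @export
tidy.cv_report <- function(x, ...) x$table

#' @rdname physiocca_tidiers
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(mean_oos_r = x$mean_oos_r,
                 weight_stability_brain = x$weight_stability_brain,
                 weight_stability_behavior = x$weight_stability_behavior,
                 best_fold = x$best_fold,
                 p_mean = if (is.null(x$perm)) NA_real_ else
                   x$perm$p_mean,
                 any_fold_significant = if (is.null(x$perm)) NA else
                   x$perm$any_fold_significant)
}

#' @rdname physiocca_tidiers
#' @export
tidy.network_icc_summary <- function(x, ...) x$networks

#' @rdname physiocca_tidiers
#' @export
glance.network_icc_summary <- function(x, ...) {
  tibble::tibble(kruskal_h = x$kruskal_h, p_value = x$p_value,
                 n_networks = nrow(x$networks))
}
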