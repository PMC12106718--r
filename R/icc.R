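# Per-ROI spatial consistency between two topography sets via two-way
# random-effects ANOVA mean squares, plus network-level comparison.

icc_mean_squares <- function(a, b) {
  # a, b: participants x ROI; per ROI an n x 2 table (rows =
  # participants, columns = measures)
  n <- nrow(a)
  k <- 2
  grand <- (colMeans(a) + colMeans(b)) / 2
  row_mean <- (a + b) / 2
  sst <- colSums(sweep(a, 2, grand)^2) + colSums(sweep(b, 2, grand)^2)
  ssr <- k * colSums(sweep(row_mean, 2, grand)^2)
  col_mean_a <- colMeans(a)
  col_mean_b <- colMeans(b)
  ssc <- n * ((col_mean_a - grand)^2 + (col_mean_b - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k, sst = sst)
}

#' Two-way random-effects ICC per ROI
#'
#' For every ROI, the two topography values across participants form an
#' n x 2 table (rows = participants, columns = measures) whose two-way
#' ANOVA mean squares give the intraclass correlation:
#' `ICC = sigma_r^2 / (sigma_r^2 + sigma_e^2)` with
#' `sigma_r^2 = MSR - MSE` and `sigma_e^2 = MSE`.
#'
#' The default `"paper"` variant uses the row-variance estimate exactly as
#' written above, without the conventional division of `MSR - MSE` by the
#' number of measures; the Shrout-Fleiss consistency `"icc_c1"` =
#' `(MSR - MSE) / (MSR + (k-1) MSE)` and absolute-agreement `"icc_a1"`
#' variants are selectable. Negative row-variance estimates are floored at
#' zero. When lists of matrices are supplied (one per scan/session), the
#' ICC is computed per session and averaged.
#'
#' @param a,b participants x ROI matrices (same participants, same ROIs),
#'   or lists of such matrices for multi-session averaging.
#' @param variant `"paper"`, `"icc_c1"` or `"icc_a1"`.
#' @return An `icc_map`: tibble with per-ROI `icc`, `var_rows`,
#'   `var_error`, plus the variant and participant count.
#' @export
icc_two_way <- function(a, b, variant = c("paper", "icc_c1", "icc_a1")) {
  variant <- match.arg(variant)
  if (is.list(a) && !is.matrix(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    maps <- Map(function(ai, bi) icc_two_way(ai, bi, variant), a, b)
    out <- maps[[1]]
    iccs <- vapply(maps, function(m) m$table$icc, numeric(nrow(out$table)))
    out$table$icc <- rowMeans(iccs)
    out$n_sessions <- length(maps)
    return(out)
  }
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    abort_arg("topography sets must have identical dimensions")
  if (nrow(a) < 3) abort_arg("need at least 3 participants")
  ms <- icc_mean_squares(a, b)
  var_rows <- pmax(ms$msr - ms$mse, 0)
  icc <- switch(variant,
    paper = var_rows / (var_rows + ms$mse),
    icc_c1 = (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse),
    icc_a1 = (ms$msr - ms$mse) /
      (ms$msr + (ms$k - 1) * ms$mse +
         ms$k / ms$n * (ms$msc - ms$mse)))
  degenerate <- ms$sst == 0
  icc[degenerate] <- NA_real_
  if (any(degenerate))
    warning(sum(degenerate), " ROI(s) with zero total variance; ICC NA")
  roi <- colnames(a) %||% paste0("roi_", seq_len(ncol(a)))
  structure(list(
    table = tibble::tibble(roi = roi, icc = unname(icc),
                           var_rows = unname(var_rows),
                           var_error = unname(ms$mse),
                           msr = unname(ms$msr), msc = unname(ms$msc)),
    variant = variant, n_participants = ms$n, n_sessions = 1L),
    class = "icc_map")
}

#' @export
print.icc_map <- function(x, ...) {
  cat(sprintf("<icc_map: %d ROIs, variant = %s, n = %d, median ICC %.3f>\n",
              nrow(x$table), x$variant, x$n_participants,
              median(x$table$icc, na.rm = TRUE)))
  invisible(x)
}

#' Network-level summary of an ICC map
#'
#' Fisher z-transforms per-ROI ICC values, groups them by network using
#' the atlas table, and compares networks with a Kruskal-Wallis rank test.
#' Networks with fewer than 2 ROIs are excluded with a warning.
#'
#' @param icc an `icc_map` from [icc_two_way()].
#' @param atlas tibble with columns `roi` and `network` covering all ROIs.
#' @return A `network_icc_summary`: per-network tibble (median ICC, mean
#'   Fisher-z, ROI count) plus the Kruskal-Wallis H statistic and p-value.
#' @export
network_icc_summary <- function(icc, atlas) {
  stopifnot(inherits(icc, "icc_map"))
  atlas <- tibble::as_tibble(atlas)
  if (!all(c("roi", "network") %in% names(atlas)))
    abort_arg("atlas needs columns roi and network")
  d <- dplyr::inner_join(icc$table, atlas, by = "roi")
  if (nrow(d) < nrow(icc$table))
    abort_arg("atlas does not cover all ROIs")
  d <- d[!is.na(d$icc), ]
  d$z <- fisher_z(d$icc)
  sizes <- table(d$network)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding network(s) with < 2 ROIs: ",
            paste(small, collapse = ", "))
    d <- d[!d$network %in% small, ]
  }
  if (length(unique(d$network)) < 2)
    abort_arg("need at least 2 networks")
  kw <- kruskal.test(d$z, factor(d$network))
  per_net <- d |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(n_roi = dplyr::n(),
                     median_icc = median(.data$icc),
                     mean_z = mean(.data$z), .groups = "drop")
  structure(list(networks = per_net,
                 kruskal_h = unname(kw$statistic),
                 p_value = kw$p.value, per_roi = d),
            class = "network_icc_summary")
}

#' @export
print.network_icc_summary <- function(x, ...) {
  cat(sprintf("<network_icc_summary: %d networks, H = %.3f, p = %.3g>\n",
              nrow(x$networks), x$kruskal_h, x$p_value))
  print(x$networks)
  invisible(x)
}
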