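# Global signal, lag optimization against physiological measures, and
# per-participant Fisher-z coupling topographies.

#' Global signal of a run
#'
#' Unweighted mean BOLD time series across all regions of interest.
#'
#' @param run a [run_series()].
#' @return A [frame_series()] labelled `"GS"`.
#' @export
compute_global_signal <- function(run) {
  stopifnot(inherits(run, "run_series"))
  if (nrow(run$bold) == 0) abort_arg("empty ROI set")
  frame_series(colMeans(run$bold), run$tr_s, "GS")
}

#' Truncate frame edges
#'
#' Removes the first and last `n_edge` frames (default 10), discarding
#' filter and equilibration transients before correlation.
#'
#' @param x a [frame_series()], [run_series()] or numeric vector.
#' @param n_edge frames removed from each end.
#' @return Same type as the input, shortened by `2 * n_edge`.
#' @export
truncate_series <- function(x, n_edge = 10) {
  n_edge <- as.integer(n_edge)
  if (n_edge < 0) abort_arg("n_edge must be >= 0")
  if (n_edge == 0) return(x)
  if (inherits(x, "frame_series")) {
    n <- length(x$values)
    if (n <= 2 * n_edge) abort_arg("series too short to truncate")
    return(frame_series(x$values[(n_edge + 1):(n - n_edge)], x$tr_s,
                        x$measure))
  }
  if (inherits(x, "run_series")) {
    n <- ncol(x$bold)
    if (n <= 2 * n_edge) abort_arg("run too short to truncate")
    return(run_series(x$bold[, (n_edge + 1):(n - n_edge), drop = FALSE],
                      x$tr_s, x$roi_ids))
  }
  n <- length(x)
  if (n <= 2 * n_edge) abort_arg("series too short to truncate")
  x[(n_edge + 1):(n - n_edge)]
}

series_values <- function(x) if (inherits(x, "frame_series")) x$values else x

# correlation between reference shifted backward by `lag` frames and the
# target: reference at time t - lag is paired with target at t, computed
# on the overlapping segment only (no padding)
lagged_cor <- function(target, reference, lag) {
  n <- length(target)
  if (lag >= 0) {
    a <- target[(1 + lag):n]
    b <- reference[1:(n - lag)]
  } else {
    a <- target[1:(n + lag)]
    b <- reference[(1 - lag):n]
  }
  if (length(a) < 3) return(NA_real_)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

new_lag_estimate <- function(lag_frames, tr_s, flip, profile) {
  structure(list(lag_frames = lag_frames, lag_s = lag_frames * tr_s,
                 flip = flip, tr_s = tr_s, xcorr_profile = profile),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate: %+d frames (%.3g s), flip = %s>\n",
              x$lag_frames, x$lag_s, x$flip))
  invisible(x)
}

#' Group-level lag between the global signal and a physiological measure
#'
#' Cross-correlates each run's (already truncated) global signal with its
#' physiological frame series over integer-frame lags spanning up to
#' `max_lag_s` (72 s by default) in both directions. Correlations are
#' computed on the overlapping segment of each lag, averaged across runs
#' within participant and then across participants, and the lag with the
#' strongest absolute mean correlation is returned; a negative mean
#' correlation at that lag sets `flip = TRUE` (the measure couples
#' inverted, as RVT does). Ties in |correlation| resolve toward the
#' smaller |lag|. A positive lag means the physiological sample at
#' `t - lag` is paired with BOLD at `t` ("shifted backward").
#'
#' @param gs_by_run list of global-signal [frame_series()] (or numeric
#'   vectors), one per run.
#' @param physio_by_run matching list of physiological frame series.
#' @param participant optional vector assigning each run to a participant;
#'   default treats every run as its own participant.
#' @param max_lag_s lag search half-width in seconds.
#' @param tr_s repetition time; taken from the series when omitted.
#' @return A `lag_estimate` with the per-lag mean-correlation profile.
#' @export
estimate_group_lag <- function(gs_by_run, physio_by_run, participant = NULL,
                               max_lag_s = 72, tr_s = NULL) {
  if (length(gs_by_run) != length(physio_by_run))
    abort_arg("gs_by_run and physio_by_run must pair up")
  if (inherits(gs_by_run, "frame_series")) gs_by_run <- list(gs_by_run)
  if (inherits(physio_by_run, "frame_series"))
    physio_by_run <- list(physio_by_run)
  tr_s <- tr_s %||% (if (inherits(gs_by_run[[1]], "frame_series"))
    gs_by_run[[1]]$tr_s else abort_arg("tr_s required for bare vectors"))
  participant <- participant %||% seq_along(gs_by_run)
  max_lag <- round(max_lag_s / tr_s)
  lags <- seq(-max_lag, max_lag)
  per_run <- vapply(seq_along(gs_by_run), function(i) {
    g <- series_values(gs_by_run[[i]])
    p <- series_values(physio_by_run[[i]])
    if (length(g) != length(p)) abort_arg("run ", i, ": unequal lengths")
    if (length(g) - max_lag < 3)
      abort_arg("overlap shorter than 3 frames at extreme lag")
    vapply(lags, function(l) lagged_cor(g, p, l), numeric(1))
  }, numeric(length(lags)))
  per_run <- matrix(per_run, nrow = length(lags))
  # average within participant, then across participants
  by_part <- vapply(unique(participant), function(pp) {
    rowMeans(per_run[, participant == pp, drop = FALSE], na.rm = TRUE)
  }, numeric(length(lags)))
  mean_r <- rowMeans(matrix(by_part, nrow = length(lags)), na.rm = TRUE)
  if (all(!is.finite(mean_r)))
    abort_arg("degenerate input: no finite cross-correlations ",
              "(zero-variance series?)")
  ord <- order(-abs(mean_r), abs(lags), lags)
  best <- ord[1]
  profile <- tibble::tibble(lag_frames = lags, lag_s = lags * tr_s,
                            mean_r = mean_r)
  new_lag_estimate(lags[best], tr_s, unname(mean_r[best] < 0), profile)
}

#' Individually optimized lag for one participant
#'
#' Same search as [estimate_group_lag()] restricted to one participant's
#' runs (averaged across that participant's runs only).
#'
#' @inheritParams estimate_group_lag
#' @return A `lag_estimate`.
#' @export
estimate_individual_lag <- function(gs_by_run, physio_by_run,
                                    max_lag_s = 72, tr_s = NULL) {
  estimate_group_lag(gs_by_run, physio_by_run,
                     participant = rep(1L, length(gs_by_run)),
                     max_lag_s = max_lag_s, tr_s = tr_s)
}

#' Per-participant coupling topography
#'
#' Correlates every ROI's BOLD time series with a reference series
#' (global signal or a lag-aligned physiological measure), Fisher
#' z-transforms the correlations (with `|r|` clipped at `1 - 1e-7`), and
#' averages the per-run vectors into one topography. When a
#' [estimate_group_lag()] result (or explicit `lag_frames` / `flip`) is
#' supplied, the reference is first negated if flipped and shifted
#' backward by the lag, and correlations use the overlapping frames only.
#'
#' @param runs list of (truncated) [run_series()] for one participant.
#' @param reference_by_run matching list of (truncated) reference series.
#' @param lag a `lag_estimate`, an integer lag in frames, or `NULL` for
#'   zero lag.
#' @param flip negate the reference before correlating; overridden by a
#'   `lag_estimate`'s own flip.
#' @param measure label stored on the result, e.g. `"GSCORR"`.
#' @return A `topography`: named per-ROI Fisher-z vector with measure and
#'   run-count metadata. ROIs with zero variance in every run come back
#'   `NA` with a warning.
#' @export
compute_coupling_map <- function(runs, reference_by_run, lag = NULL,
                                 flip = FALSE, measure = "GSCORR") {
  if (inherits(runs, "run_series")) runs <- list(runs)
  if (inherits(reference_by_run, "frame_series") ||
      is.numeric(reference_by_run))
    reference_by_run <- list(reference_by_run)
  if (length(runs) != length(reference_by_run))
    abort_arg("runs and reference_by_run must pair up")
  lag_frames <- 0L
  if (inherits(lag, "lag_estimate")) {
    lag_frames <- lag$lag_frames
    flip <- lag$flip
  } else if (!is.null(lag)) lag_frames <- as.integer(lag)
  zmats <- lapply(seq_along(runs), function(i) {
    run <- runs[[i]]
    stopifnot(inherits(run, "run_series"))
    ref <- series_values(reference_by_run[[i]])
    n <- ncol(run$bold)
    if (length(ref) != n)
      abort_arg("run ", i, ": reference not aligned to run frames")
    if (flip) ref <- -ref
    if (lag_frames >= 0) {
      bold <- run$bold[, (1 + lag_frames):n, drop = FALSE]
      ref <- ref[1:(n - lag_frames)]
    } else {
      bold <- run$bold[, 1:(n + lag_frames), drop = FALSE]
      ref <- ref[(1 - lag_frames):n]
    }
    if (length(ref) < 3) abort_arg("overlap shorter than 3 frames")
    if (sd(ref) == 0) abort_arg("zero-variance reference in run ", i)
    rs <- suppressWarnings(as.numeric(cor(t(bold), ref)))
    rs[apply(bold, 1, sd) == 0] <- NA_real_
    fisher_z(rs)
  })
  zmat <- do.call(cbind, zmats)
  vals <- rowMeans(zmat, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  names(vals) <- runs[[1]]$roi_ids
  if (all(is.na(vals))) abort_arg("all ROIs degenerate")
  if (anyNA(vals))
    warning(sum(is.na(vals)), " ROI(s) had zero variance; set to NA")
  structure(list(values = vals, measure = measure,
                 n_runs_averaged = length(runs)),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography: %s, %d ROIs, %d run(s) averaged>\n",
              x$measure, length(x$values), x$n_runs_averaged))
  invisible(x)
}
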