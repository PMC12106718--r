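#' Physiological trace container
#'
#' A raw or cleaned one-channel physiological recording (respiratory belt
#' or pulse oximetry) sampled at a fixed rate.
#'
#' @param samples numeric vector, one sample per time point.
#' @param fs sampling rate in Hz.
#' @param kind `"respiratory"` or `"cardiac"`.
#' @param state `"raw"` or `"cleaned"`.
#' @return An object of class `physio_trace`.
#' @export
physio_trace <- function(samples, fs, kind = c("respiratory", "cardiac"),
                         state = c("raw", "cleaned")) {
  kind <- match.arg(kind)
  state <- match.arg(state)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    abort_arg("fs must be a positive scalar (Hz)")
  if (!is.numeric(samples) || length(samples) < 2)
    abort_arg("samples must be a numeric vector")
  structure(list(samples = as.numeric(samples), fs = fs,
                 kind = kind, state = state),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("<physio_trace: %s, %s, %.6g s @ %g Hz (%d samples)>\n",
              x$kind, x$state, length(x$samples) / x$fs, x$fs,
              length(x$samples)))
  invisible(x)
}

#' Frame-grid series container
#'
#' One value per fMRI frame, e.g. a physiological measure resampled to the
#' repetition-time grid or the global signal itself.
#'
#' @param values numeric vector, one value per frame.
#' @param tr_s repetition time in seconds.
#' @param measure label, e.g. `"RVT"`, `"ENV"`, `"RV"`, `"HR"`, `"GS"`.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(values, tr_s, measure = "GS") {
  if (!is.numeric(tr_s) || length(tr_s) != 1 || tr_s <= 0)
    abort_arg("tr_s must be a positive scalar (seconds)")
  if (!all(is.finite(values)))
    abort_arg("frame series values must all be finite")
  structure(list(values = as.numeric(values), tr_s = tr_s,
                 measure = measure),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series: %s, %d frames, TR %g s>\n",
              x$measure, length(x$values), x$tr_s))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$values)

#' BOLD run container
#'
#' One run's region-of-interest by frame BOLD matrix with its repetition
#' time.
#'
#' @param bold numeric matrix, ROI rows by frame columns.
#' @param tr_s repetition time in seconds.
#' @param roi_ids optional ROI identifiers (defaults to rownames or
#'   `roi_1 ...`).
#' @return An object of class `run_series`.
#' @export
run_series <- function(bold, tr_s, roi_ids = NULL) {
  bold <- as.matrix(bold)
  if (!is.numeric(bold) || nrow(bold) < 1)
    abort_arg("bold must be a numeric ROI x frame matrix")
  if (anyNA(bold) || !all(is.finite(bold)))
    abort_arg("bold matrix contains non-finite values")
  if (is.null(roi_ids))
    roi_ids <- rownames(bold) %||% paste0("roi_", seq_len(nrow(bold)))
  if (length(roi_ids) != nrow(bold))
    abort_arg("roi_ids length must match ROI count")
  rownames(bold) <- roi_ids
  structure(list(bold = bold, tr_s = tr_s, roi_ids = roi_ids),
            class = "run_series")
}

#' @export
print.run_series <- function(x, ...) {
  cat(sprintf("<run_series: %d ROIs x %d frames, TR %g s>\n",
              nrow(x$bold), ncol(x$bold), x$tr_s))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
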