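# Physiological preprocessing: trace cleaning and derivation of RVT, ENV,
# RV and instantaneous heart rate, plus resampling to the fMRI frame grid.

# forward-backward Butterworth with odd-reflection padding, so boundary
# discontinuities do not ring into the trace
butter_zerophase <- function(x, fs, w, type) {
  flt <- signal::butter(2, w / (fs / 2), type = type)
  n <- length(x)
  p <- min(n - 1, max(12L, round(3 * fs)))
  head_pad <- 2 * x[1] - x[(p + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- as.numeric(signal::filtfilt(flt, c(head_pad, x, tail_pad)))
  y[(p + 1):(p + n)]
}

zscore_vec <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    abort_arg("degenerate input: zero-variance trace")
  (x - mean(x)) / s
}

# flag samples deviating more than nmad scaled MADs from the local median
local_mad_outliers <- function(x, width, nmad = 3) {
  mm <- .slide_med_mad(x, as.integer(width))
  dev <- abs(x - mm[, 1])
  thr <- nmad * MAD_SCALE * mm[, 2]
  # MAD = 0 segments (locally constant) are treated as non-outliers
  dev > thr & thr > 0
}

#' Clean a respiratory-belt trace
#'
#' Standardizes the belt signal and removes transient artefacts. The fixed
#' pipeline order is: z-score, linear detrend, replacement of samples more
#' than 3 scaled median absolute deviations from the local median in a
#' 0.3 s centered window (120 samples at 400 Hz) by linear interpolation,
#' zero-phase low-pass filtering at 5 Hz with a second-order Butterworth
#' filter, and a final z-score. Filtering is forward-backward so the
#' cleaned trace keeps zero phase shift; any phase distortion here would
#' bias the downstream lag search.
#'
#' @param raw a [physio_trace()] with `kind = "respiratory"`,
#'   `state = "raw"`.
#' @param outlier_window_s width of the local-median window in seconds.
#' @param lowpass_hz low-pass corner frequency in Hz.
#' @return A cleaned `physio_trace` with mean 0 and SD 1.
#' @export
clean_respiratory_trace <- function(raw, outlier_window_s = 0.3,
                                    lowpass_hz = 5) {
  stopifnot(inherits(raw, "physio_trace"))
  if (raw$kind != "respiratory") abort_arg("trace kind must be respiratory")
  if (raw$state != "raw") abort_arg("trace already cleaned")
  x <- raw$samples
  if (length(x) < raw$fs) abort_arg("trace shorter than filter warm-up")
  x <- zscore_vec(x)
  t <- seq_along(x)
  x <- as.numeric(lm.fit(cbind(1, t), x)$residuals)
  width <- max(3L, round(outlier_window_s * raw$fs))
  x <- interp_replace(x, local_mad_outliers(x, width))
  x <- butter_zerophase(x, raw$fs, lowpass_hz, "low")
  x <- zscore_vec(x)
  physio_trace(x, raw$fs, "respiratory", "cleaned")
}

#' Clean a pulse-oximetry trace
#'
#' z-scores then band-pass filters the cardiac signal between 0.3 and
#' 10 Hz (zero-phase, second-order Butterworth), removing slow drift and
#' high-frequency noise while keeping the pulsatile waveform.
#'
#' @param raw a [physio_trace()] with `kind = "cardiac"`.
#' @param band two-element numeric, pass band in Hz.
#' @return A cleaned `physio_trace`.
#' @export
clean_cardiac_trace <- function(raw, band = c(0.3, 10)) {
  stopifnot(inherits(raw, "physio_trace"))
  if (raw$kind != "cardiac") abort_arg("trace kind must be cardiac")
  x <- raw$samples
  if (length(x) < raw$fs) abort_arg("trace shorter than filter warm-up")
  x <- zscore_vec(x)
  x <- butter_zerophase(x, raw$fs, band, "pass")
  physio_trace(x, raw$fs, "cardiac", "cleaned")
}

# analytic-signal magnitude via the frequency-domain Hilbert transform
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

envelope_from_extrema <- function(x, idx) {
  approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

find_extrema <- function(x, fs, min_dist_s, min_height = NULL) {
  args <- list(x, minpeakdistance = max(1L, round(min_dist_s * fs)))
  if (!is.null(min_height)) args$minpeakheight <- min_height
  p <- do.call(pracma::findpeaks, args)
  if (is.null(p)) integer(0) else sort(p[, 2])
}

#' Derive a respiration measure from a cleaned belt trace
#'
#' Three summary measures of breathing depth and variability, all at the
#' trace's native sampling rate:
#' * `rvt` (respiration volume per time): difference between the upper and
#'   lower signal envelopes, with envelopes obtained by detecting peaks and
#'   troughs (minimum spacing 1 s, since breathing stays below 1 Hz),
#'   linearly interpolating between extrema and clamping the edges to the
#'   nearest extremum.
#' * `env`: sliding-window maximum of the rectified trace over a 10 s
#'   window (Hilbert-magnitude variant behind `envelope_method`).
#' * `rv`: sliding-window standard deviation over a 6 s window.
#'
#' Sliding windows shrink at the boundaries rather than padding.
#'
#' @param trace cleaned respiratory [physio_trace()].
#' @param measure `"rvt"`, `"env"` or `"rv"`.
#' @param window_s window in seconds (ignored by `rvt`; defaults: 10 s for
#'   `env`, 6 s for `rv`).
#' @param envelope_method for `env`: `"max"` rectified-max (default) or
#'   `"hilbert"` analytic-magnitude before the window maximum.
#' @param min_breath_s minimum peak/trough spacing for `rvt`, seconds.
#' @return numeric vector, same length as the input trace.
#' @export
derive_respiration_measure <- function(trace,
                                       measure = c("rvt", "env", "rv"),
                                       window_s = NULL,
                                       envelope_method = c("max", "hilbert"),
                                       min_breath_s = 1) {
  stopifnot(inherits(trace, "physio_trace"))
  measure <- match.arg(measure)
  envelope_method <- match.arg(envelope_method)
  if (trace$state != "cleaned") abort_arg("trace must be cleaned first")
  x <- trace$samples
  fs <- trace$fs
  if (length(x) < fs * 10) abort_arg("trace shorter than 10 s")
  if (measure == "rvt") {
    # the cleaned trace is zero-mean: inspiratory peaks lie above zero and
    # expiratory troughs below, which rejects ripple extrema on the wrong
    # side of the baseline
    peaks <- find_extrema(x, fs, min_breath_s, min_height = 0)
    troughs <- find_extrema(-x, fs, min_breath_s, min_height = 0)
    if (length(peaks) < 3 || length(troughs) < 3)
      abort_arg("degenerate input: fewer than 3 breathing cycles detected")
    upper <- envelope_from_extrema(x, peaks)
    lower <- envelope_from_extrema(x, troughs)
    return(pmax(upper - lower, 0))
  }
  window_s <- window_s %||% if (measure == "env") 10 else 6
  width <- max(3L, round(window_s * fs))
  if (measure == "env") {
    mag <- if (envelope_method == "hilbert") hilbert_envelope(x) else abs(x)
    return(.slide_max(mag, as.integer(width)))
  }
  .slide_sd(x, as.integer(width))
}

#' Instantaneous heart rate from a cleaned cardiac trace
#'
#' Detects pulse peaks with a minimum inter-peak distance of 0.3 s,
#' converts inter-beat intervals to beats per minute (60 / IBI), assigns
#' each rate to the interval midpoint and linearly interpolates to the
#' sample grid. Beat-level outliers more than 3 scaled MADs from the local
#' 30 s median, or outside the physiological range, are replaced by
#' interpolation across neighbouring beats before gridding.
#'
#' @param trace cleaned cardiac [physio_trace()].
#' @param min_peak_dist_s minimum inter-peak distance, seconds.
#' @param hr_range allowed heart-rate range in bpm.
#' @param outlier_window_s window for the local beat median, seconds.
#' @return numeric vector of bpm values, one per sample of the input.
#' @export
compute_heart_rate <- function(trace, min_peak_dist_s = 0.3,
                               hr_range = c(30, 180),
                               outlier_window_s = 30) {
  stopifnot(inherits(trace, "physio_trace"))
  if (trace$kind != "cardiac") abort_arg("trace kind must be cardiac")
  if (trace$state != "cleaned") abort_arg("trace must be cleaned first")
  x <- trace$samples
  fs <- trace$fs
  # require pulses to rise clearly above the band-passed baseline so
  # filter ringing between beats is not detected
  peaks <- find_extrema(x, fs, min_peak_dist_s,
                        min_height = 0.3 * quantile(x, 0.99))
  if (length(peaks) < 2)
    abort_arg("degenerate input: fewer than 2 pulse peaks detected")
  ibi <- diff(peaks) / fs
  hr <- 60 / ibi
  mid <- (peaks[-1] + peaks[-length(peaks)]) / 2
  # beat-level outlier replacement within a +/- half-window neighbourhood
  bad <- hr < hr_range[1] | hr > hr_range[2]
  if (length(hr) >= 3) {
    half <- outlier_window_s * fs / 2
    for (i in seq_along(hr)) {
      nb <- hr[abs(mid - mid[i]) <= half]
      med <- median(nb)
      madv <- MAD_SCALE * median(abs(nb - med))
      if (madv > 0 && abs(hr[i] - med) > 3 * madv) bad[i] <- TRUE
    }
  }
  if (all(bad)) abort_arg("degenerate input: all beat intervals rejected")
  hr <- interp_replace(hr, bad)
  hr <- pmin(pmax(hr, hr_range[1]), hr_range[2])
  if (length(hr) == 1) return(rep(hr, length(x)))
  approx(mid, hr, xout = seq_along(x), rule = 2)$y
}

#' Resample a sample-rate series to the fMRI frame grid
#'
#' Block-averages samples within each repetition-time window, matching the
#' temporal-averaging convention used to bring 400 Hz physiological
#' measures onto a 1200-frame, TR = 0.72 s run (400 x 0.72 = 288 samples
#' per frame).
#'
#' @param x numeric vector sampled at `fs`.
#' @param fs sampling rate in Hz.
#' @param n_frames number of fMRI frames.
#' @param tr_s repetition time in seconds.
#' @param measure label for the returned [frame_series()].
#' @return A [frame_series()] of length `n_frames`.
#' @export
resample_to_frames <- function(x, fs, n_frames, tr_s, measure = "RVT") {
  if (fs * tr_s < 1) abort_arg("fewer than one sample per frame")
  needed <- round(n_frames * tr_s * fs)
  if (length(x) < needed - round(fs * tr_s))
    abort_arg(sprintf("series too short: %d samples, %d needed",
                      length(x), needed))
  bounds <- round(seq(0, n_frames) * fs * tr_s)
  bounds <- pmin(bounds, length(x))
  vals <- vapply(seq_len(n_frames), function(k) {
    lo <- bounds[k] + 1
    hi <- bounds[k + 1]
    if (hi < lo) return(NA_real_)
    mean(x[lo:hi])
  }, numeric(1))
  # a shortfall within one frame: carry the last defined value forward
  if (anyNA(vals)) {
    last <- max(which(!is.na(vals)))
    vals[is.na(vals)] <- vals[last]
  }
  frame_series(vals, tr_s, measure)
}
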