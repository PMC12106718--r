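# Synthetic cohorts with known ground truth: a shared global component
# with heterogeneous regional loadings, a flipped + lagged respiratory
# coupling map, a planted canonical mode linking topography to behavior,
# and twin-family blocks. Every downstream stage has a recoverable answer.

#' Simulated respiratory-belt trace
#'
#' Quasi-periodic breathing carrier (~0.3 Hz) whose amplitude is
#' modulated at an infra-slow rate (~0.03 Hz), emulating the end-tidal
#' CO2-paced depth fluctuations that drive RVT:
#' `(1 + mod_depth * sin(2*pi*mod_hz*t + mod_phase)) *
#'  sin(2*pi*carrier_hz*t + carrier_phase) + noise`.
#'
#' @param duration_s trace duration in seconds.
#' @param fs sampling rate in Hz (must exceed twice the carrier).
#' @param carrier_hz breathing rate, Hz.
#' @param mod_hz amplitude-modulation rate, Hz.
#' @param mod_depth modulation depth in `[0, 1)`.
#' @param noise_sd additive white-noise SD.
#' @param carrier_phase,mod_phase phases in radians.
#' @param seed optional integer seed for the noise.
#' @return A raw respiratory [physio_trace()] with the analytic amplitude
#'   envelope stored in `attr(, "envelope")`.
#' @export
generate_respiratory_trace <- function(duration_s, fs, carrier_hz = 0.3,
                                       mod_hz = 0.03, mod_depth = 0.5,
                                       noise_sd = 0.05,
                                       carrier_phase = 0, mod_phase = 0,
                                       seed = NULL) {
  if (duration_s <= 0 || fs <= 0) abort_arg("duration_s and fs must be > 0")
  if (fs <= 2 * carrier_hz) abort_arg("fs must exceed twice the carrier")
  if (mod_depth < 0 || mod_depth >= 1) abort_arg("mod_depth must be in [0, 1)")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  env <- 1 + mod_depth * sin(2 * pi * mod_hz * t + mod_phase)
  x <- env * sin(2 * pi * carrier_hz * t + carrier_phase)
  if (noise_sd > 0)
    x <- x + with_seed(seed, rnorm(n, 0, noise_sd))
  out <- physio_trace(x, fs, "respiratory", "raw")
  attr(out, "envelope") <- env
  out
}

#' Simulated pulse-oximetry trace
#'
#' A train of narrow Gaussian pulses at beat times whose inter-beat
#' intervals are drawn around `60 / mean_hr_bpm`, giving identifiable
#' peaks with controllable heart-rate variability.
#'
#' @param duration_s trace duration in seconds.
#' @param fs sampling rate in Hz (>= 50 for resolvable pulses).
#' @param mean_hr_bpm mean heart rate, beats per minute.
#' @param hr_sd_bpm per-beat heart-rate SD, bpm (0 gives a metronome).
#' @param pulse_width_s Gaussian pulse width (SD), seconds.
#' @param noise_sd additive white-noise SD.
#' @param seed optional integer seed.
#' @return A raw cardiac [physio_trace()]; the sampled inter-beat
#'   intervals and beat times are stored as attributes `"ibis"` and
#'   `"beat_times"`.
#' @export
generate_cardiac_trace <- function(duration_s, fs, mean_hr_bpm = 70,
                                   hr_sd_bpm = 3, pulse_width_s = 0.05,
                                   noise_sd = 0.01, seed = NULL) {
  if (mean_hr_bpm <= 0) abort_arg("mean_hr_bpm must be > 0")
  if (hr_sd_bpm < 0) abort_arg("hr_sd_bpm must be >= 0")
  if (fs < 50) abort_arg("fs must be >= 50 Hz for resolvable pulses")
  if (duration_s <= 0) abort_arg("duration_s must be > 0")
  with_seed(seed, {
    max_beats <- ceiling(duration_s * mean_hr_bpm / 60 * 2) + 10
    hr <- pmax(20, rnorm(max_beats, mean_hr_bpm, hr_sd_bpm))
    ibis <- 60 / hr
    beats <- 0.2 + cumsum(c(0, ibis))
    keep <- beats <= duration_s - 0.1
    beats <- beats[keep]
    ibis <- diff(beats)
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    half <- ceiling(4 * pulse_width_s * fs)
    for (b in beats) {
      ctr <- round(b * fs) + 1
      idx <- max(1, ctr - half):min(n, ctr + half)
      x[idx] <- x[idx] + exp(-0.5 * ((t[idx] - b) / pulse_width_s)^2)
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    out <- physio_trace(x, fs, "cardiac", "raw")
    attr(out, "ibis") <- ibis
    attr(out, "beat_times") <- beats
    out
  })
}

#' Ground-truth configuration for a synthetic cohort
#'
#' Collects the planted quantities the generator embeds: the lag and sign
#' of the respiratory coupling, the respiratory coupling map's relation to
#' the global loadings, the strength of participant-level coupling
#' variation (the individual-difference signal the canonical mode rides
#' on), the planted canonical correlation, behavioral loadings and family
#' structure.
#'
#' @param true_lag_frames respiratory coupling lag, frames (BOLD lags the
#'   flipped RVT by this many frames).
#' @param hr_lag_frames cardiac coupling lag, frames.
#' @param true_canonical_r planted correlation between the topographic and
#'   behavioral latents, in `[0, 1]`.
#' @param coupling `"matched"` (respiratory map proportional to the global
#'   loadings), `"independent"` (mean-zero map unrelated to the
#'   loadings), or `"none"`.
#' @param coupling_scale respiratory map magnitude relative to the global
#'   loadings.
#' @param coupling_strength_sd SD of the participant-level coupling gain
#'   around 1.
#' @param hr_coupling_scale cardiac map magnitude (0 disables).
#' @param family_effect fraction of latent variance shared within a
#'   family.
#' @param mz_pair_fraction,dz_pair_fraction fractions of participants
#'   placed in monozygotic / dizygotic twin pairs (remainder are
#'   singletons).
#' @param n_behaviors number of behavioral measures.
#' @param behavior_noise_sd residual SD of each behavioral measure.
#' @param bold_noise_sd idiosyncratic BOLD noise SD.
#' @return A list of class `cohort_truth_config`.
#' @export
cohort_truth_config <- function(true_lag_frames = 16L, hr_lag_frames = 1L,
                                true_canonical_r = 0.7,
                                coupling = c("matched", "independent",
                                             "none"),
                                coupling_scale = 0.5,
                                coupling_strength_sd = 0.35,
                                hr_coupling_scale = 0,
                                family_effect = 0.3,
                                mz_pair_fraction = 0.3,
                                dz_pair_fraction = 0.2,
                                n_behaviors = 40,
                                behavior_noise_sd = 0.8,
                                bold_noise_sd = 1) {
  coupling <- match.arg(coupling)
  if (true_lag_frames < 0) abort_arg("true_lag_frames must be >= 0")
  if (true_canonical_r < 0 || true_canonical_r > 1)
    abort_arg("true_canonical_r must be in [0, 1]")
  if (family_effect < 0 || family_effect >= 1)
    abort_arg("family_effect must be in [0, 1)")
  structure(as.list(environment()), class = "cohort_truth_config")
}

# correlated latent pair (t, b) with family-shared components: each block
# of family members shares one draw; cor(t, b) = rho at both levels, so
# the marginal correlation is rho regardless of family_effect
draw_latents <- function(family_id, rho, family_effect) {
  fam <- unique(family_id)
  nf <- length(fam)
  n <- length(family_id)
  mix <- function(m) cbind(m[, 1], rho * m[, 1] + sqrt(1 - rho^2) * m[, 2])
  fam_draw <- mix(matrix(rnorm(2 * nf), ncol = 2))
  ind_draw <- mix(matrix(rnorm(2 * n), ncol = 2))
  fi <- match(family_id, fam)
  w <- sqrt(family_effect)
  v <- sqrt(1 - family_effect)
  list(topo = w * fam_draw[fi, 1] + v * ind_draw[, 1],
       behavior = w * fam_draw[fi, 2] + v * ind_draw[, 2])
}

assign_families <- function(n, mz_frac, dz_frac) {
  n_mz <- floor(n * mz_frac / 2)
  n_dz <- floor(n * dz_frac / 2)
  sizes <- c(rep(2L, n_mz + n_dz), rep(1L, n - 2 * (n_mz + n_dz)))
  fam_id <- rep(seq_along(sizes), times = sizes)
  zyg <- c(rep("MZ", 2 * n_mz), rep("DZ", 2 * n_dz),
           rep("NotTwin", n - 2 * (n_mz + n_dz)))
  # shuffle participant order so families are interleaved in the roster
  ord <- sample.int(n)
  tibble::tibble(participant = sprintf("sub_%03d", seq_len(n)),
                 family_id = sprintf("fam_%03d", fam_id[ord]),
                 zygosity = zyg[ord])
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds per-participant BOLD runs as
#' `BOLD_j(t) = loading_j * g(t) + gain_i * map_j * (-RVT(t - lag)) +
#'  noise`, where `g(t)` is a shared AR(1) (phi = 0.9) global component
#' band-limited below 0.1 Hz, RVT is the analytic amplitude envelope of a
#' participant-specific modulated breathing trace, and `gain_i` is a
#' participant-level coupling strength. The same latent that drives
#' `gain_i` correlates with a behavioral latent at `true_canonical_r`,
#' planting a canonical mode; both latents carry a family random effect so
#' family-blocked permutation is consequential. Missing behavioral cells
#' are injected completely at random at `missing_rate` (default 0.93%).
#'
#' @param n_participants number of participants (>= 4).
#' @param n_roi number of ROIs (>= 2).
#' @param n_frames frames per run.
#' @param tr_s repetition time, seconds.
#' @param n_runs runs per participant.
#' @param truth_config a [cohort_truth_config()].
#' @param missing_rate fraction of behavioral cells set missing, `[0, 1)`.
#' @param physio_fs sampling rate of emitted physiological traces, Hz.
#' @param keep_traces materialize raw respiratory/cardiac traces (set
#'   `FALSE` for large cohorts where only frame-grid physiology is
#'   needed).
#' @param seed integer seed; identical seed + config reproduces the
#'   cohort bit for bit.
#' @return A `physiocca_cohort`: lists of [run_series()] and traces per
#'   participant, frame-grid physiological truth, behavior / family /
#'   atlas tibbles, and the `truth` list (global loadings, coupling map,
#'   lag, gains, latents, behavioral loadings, family blocks, MZ pairs).
#' @export
generate_cohort <- function(n_participants, n_roi, n_frames, tr_s = 0.72,
                            n_runs = 1,
                            truth_config = cohort_truth_config(),
                            missing_rate = 0.0093, physio_fs = 400,
                            keep_traces = TRUE, seed = 1) {
  tc <- truth_config
  stopifnot(inherits(tc, "cohort_truth_config"))
  if (n_participants < 4) abort_arg("n_participants must be >= 4")
  if (n_roi < 2) abort_arg("n_roi must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1)
    abort_arg("missing_rate must be in [0, 1)")
  if (n_frames <= 2 * (10 + tc$true_lag_frames))
    abort_arg("n_frames must exceed 2 * (truncation + lag)")
  with_seed(seed, {
    roi_ids <- sprintf("roi_%03d", seq_len(n_roi))
    loadings <- rnorm(n_roi, 1, 0.3)
    resp_map <- switch(tc$coupling,
      matched = tc$coupling_scale * loadings,
      independent = tc$coupling_scale * rnorm(n_roi, 0, sd(loadings)),
      none = rep(0, n_roi))
    hr_map <- if (tc$hr_coupling_scale > 0)
      tc$hr_coupling_scale * rnorm(n_roi, 0, sd(loadings)) else rep(0, n_roi)
    family <- assign_families(n_participants, tc$mz_pair_fraction,
                              tc$dz_pair_fraction)
    lat <- draw_latents(family$family_id, tc$true_canonical_r,
                        tc$family_effect)
    gain <- pmax(0.05, 1 + tc$coupling_strength_sd * lat$topo)
    duration_s <- n_frames * tr_s
    lag_s <- tc$true_lag_frames * tr_s
    hr_lag_s <- tc$hr_lag_frames * tr_s
    frame_t <- (seq_len(n_frames) - 1) * tr_s
    frame_fs <- 1 / tr_s
    lp <- signal::butter(2, min(0.99, 0.1 / (frame_fs / 2)), type = "low")
    runs <- vector("list", n_participants)
    frame_physio <- vector("list", n_participants)
    resp_traces <- if (keep_traces) vector("list", n_participants)
    card_traces <- if (keep_traces) vector("list", n_participants)
    mean_hr <- rnorm(n_participants, 65, 5)
    for (i in seq_len(n_participants)) {
      runs_i <- vector("list", n_runs)
      phys_i <- vector("list", n_runs)
      rt_i <- if (keep_traces) vector("list", n_runs)
      ct_i <- if (keep_traces) vector("list", n_runs)
      for (r in seq_len(n_runs)) {
        carrier <- rnorm(1, 0.3, 0.02)
        mod_hz <- max(0.01, rnorm(1, 0.03, 0.003))
        depth <- runif(1, 0.3, 0.6)
        ph_c <- runif(1, 0, 2 * pi)
        ph_m <- runif(1, 0, 2 * pi)
        env_at <- function(t) 1 + depth * sin(2 * pi * mod_hz * t + ph_m)
        rvt_now <- as.numeric(scale(env_at(frame_t)))
        rvt_lagged <- as.numeric(scale(env_at(frame_t - lag_s)))
        # shared global component: AR(1) then band-limited below 0.1 Hz
        g <- as.numeric(stats::filter(rnorm(n_frames + 50), 0.9,
                                      method = "recursive"))[-(1:50)]
        g <- as.numeric(scale(signal::filtfilt(lp, g)))
        # cardiac truth: instantaneous HR from a sampled IBI sequence
        hrv <- pmax(20, rnorm(ceiling(duration_s * 3), mean_hr[i], 3))
        beats <- cumsum(60 / hrv)
        beats <- beats[beats <= duration_s + 2 * hr_lag_s + 2]
        ibis <- diff(beats)
        mids <- (beats[-1] + beats[-length(beats)]) / 2
        hr_fun <- function(t) approx(mids, 60 / ibis, xout = t,
                                     rule = 2)$y
        hr_now <- as.numeric(scale(hr_fun(frame_t)))
        hr_lagged <- as.numeric(scale(hr_fun(frame_t - hr_lag_s)))
        bold <- tcrossprod(loadings, g) +
          gain[i] * tcrossprod(resp_map, -rvt_lagged) +
          tcrossprod(hr_map, hr_lagged) +
          tc$bold_noise_sd * matrix(rnorm(n_roi * n_frames), n_roi)
        rownames(bold) <- roi_ids
        runs_i[[r]] <- run_series(bold, tr_s, roi_ids)
        phys_i[[r]] <- list(rvt = frame_series(rvt_now, tr_s, "RVT"),
                            hr = frame_series(hr_now, tr_s, "HR"))
        if (keep_traces) {
          noise <- rnorm(round(duration_s * physio_fs), 0, 0.05)
          t_hi <- (seq_along(noise) - 1) / physio_fs
          rt <- env_at(t_hi) * sin(2 * pi * carrier * t_hi + ph_c) + noise
          rt_i[[r]] <- physio_trace(rt, physio_fs, "respiratory", "raw")
          n_hi <- round(duration_s * physio_fs)
          ct <- numeric(n_hi)
          half <- ceiling(0.2 * physio_fs)
          for (b in beats[beats <= duration_s - 0.05]) {
            ctr <- round(b * physio_fs) + 1
            idx <- max(1, ctr - half):min(n_hi, ctr + half)
            ct[idx] <- ct[idx] + exp(-0.5 * ((t_hi[idx] - b) / 0.05)^2)
          }
          ct_i[[r]] <- physio_trace(ct + rnorm(n_hi, 0, 0.01), physio_fs,
                                    "cardiac", "raw")
        }
      }
      runs[[i]] <- runs_i
      frame_physio[[i]] <- phys_i
      if (keep_traces) {
        resp_traces[[i]] <- rt_i
        card_traces[[i]] <- ct_i
      }
    }
    beh_load <- runif(tc$n_behaviors, 0.4, 1) *
      sample(c(-1, 1), tc$n_behaviors, replace = TRUE)
    beh <- tcrossprod(lat$behavior, beh_load) +
      tc$behavior_noise_sd * matrix(rnorm(n_participants * tc$n_behaviors),
                                    n_participants)
    if (missing_rate > 0)
      beh[matrix(runif(length(beh)) < missing_rate, nrow(beh))] <- NA
    colnames(beh) <- sprintf("beh_%02d", seq_len(tc$n_behaviors))
    behavior <- dplyr::bind_cols(
      tibble::tibble(participant = family$participant),
      tibble::as_tibble(beh))
    networks <- c("Visual", "Somatomotor", "DorsalAttention",
                  "VentralAttention", "Limbic", "Control", "Default")
    atlas <- tibble::tibble(
      roi = roi_ids,
      network = networks[1 + (seq_len(n_roi) - 1) %% length(networks)])
    mz <- family[family$zygosity == "MZ", ]
    mz_pairs <- split(mz$participant, mz$family_id)
    truth <- list(global_loadings = setNames(loadings, roi_ids),
                  resp_coupling_map = setNames(resp_map, roi_ids),
                  hr_coupling_map = setNames(hr_map, roi_ids),
                  true_lag_frames = tc$true_lag_frames,
                  hr_lag_frames = tc$hr_lag_frames,
                  flip = TRUE,
                  true_canonical_r = tc$true_canonical_r,
                  behavior_loadings = setNames(beh_load,
                                               colnames(beh)),
                  coupling_gain = setNames(gain, family$participant),
                  latent_topography = setNames(lat$topo,
                                               family$participant),
                  latent_behavior = setNames(lat$behavior,
                                             family$participant),
                  family_blocks = setNames(family$family_id,
                                           family$participant),
                  mz_pairs = mz_pairs)
    structure(list(runs = runs, frame_physio = frame_physio,
                   resp_traces = resp_traces,
                   cardiac_traces = card_traces,
                   behavior = behavior, family = family, atlas = atlas,
                   truth = truth, tr_s = tr_s, n_frames = n_frames,
                   physio_fs = physio_fs,
                   participants = family$participant),
              class = "physiocca_cohort")
  })
}

#' @export
print.physiocca_cohort <- function(x, ...) {
  cat(sprintf(paste0("<physiocca_cohort: %d participants, %d ROIs, ",
                     "%d frames x %d run(s), TR %g s>\n"),
              length(x$runs), nrow(x$runs[[1]][[1]]$bold), x$n_frames,
              length(x$runs[[1]]), x$tr_s))
  invisible(x)
}

#' Coupling topographies for every cohort participant
#'
#' Convenience driver: truncates runs and frame-grid physiology, finds the
#' group lag for physiological measures (unless given), and stacks each
#' participant's [compute_coupling_map()] into a participants x ROI
#' matrix.
#'
#' @param cohort a `physiocca_cohort`.
#' @param measure `"gscorr"`, `"rvtcorr"` or `"hrcorr"`.
#' @param lag optional `lag_estimate` or integer frames; by default 0 for
#'   GSCORR and the group-estimated lag otherwise.
#' @param n_edge frames truncated from each end before correlation.
#' @param max_lag_s lag search half-width in seconds for physiological
#'   measures.
#' @return A participants x ROI matrix of Fisher-z values with the
#'   `lag_estimate` used stored in `attr(, "lag")` and the measure in
#'   `attr(, "measure")`.
#' @export
cohort_topographies <- function(cohort,
                                measure = c("gscorr", "rvtcorr", "hrcorr"),
                                lag = NULL, n_edge = 10,
                                max_lag_s = 72) {
  measure <- match.arg(measure)
  stopifnot(inherits(cohort, "physiocca_cohort"))
  n <- length(cohort$runs)
  gs <- lapply(cohort$runs, function(rr)
    lapply(rr, function(r) truncate_series(compute_global_signal(r),
                                           n_edge)))
  trunc_runs <- lapply(cohort$runs, function(rr)
    lapply(rr, function(r) truncate_series(r, n_edge)))
  if (measure == "gscorr") {
    refs <- gs
    lag_est <- NULL
  } else {
    key <- if (measure == "rvtcorr") "rvt" else "hr"
    refs <- lapply(cohort$frame_physio, function(pp)
      lapply(pp, function(p) truncate_series(p[[key]], n_edge)))
    if (is.null(lag)) {
      part <- rep(seq_len(n), vapply(gs, length, integer(1)))
      lag_est <- estimate_group_lag(unlist(gs, recursive = FALSE),
                                    unlist(refs, recursive = FALSE),
                                    participant = part,
                                    max_lag_s = max_lag_s)
    } else if (inherits(lag, "lag_estimate")) {
      lag_est <- lag
    } else {
      lag_est <- new_lag_estimate(as.integer(lag), cohort$tr_s,
                                  measure == "rvtcorr", NULL)
    }
  }
  label <- toupper(measure)
  topo <- t(vapply(seq_len(n), function(i) {
    compute_coupling_map(trunc_runs[[i]], refs[[i]], lag = lag_est,
                         measure = label)$values
  }, numeric(nrow(cohort$runs[[1]][[1]]$bold))))
  rownames(topo) <- cohort$participants
  attr(topo, "lag") <- if (measure == "gscorr") NULL else lag_est
  attr(topo, "measure") <- label
  topo
}
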