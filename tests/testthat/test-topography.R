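test_that("global signal is the unweighted ROI mean", {
  x <- smooth_series(50, 1)
  run <- run_series(rbind(x, -x), tr_s = 0.72)
  expect_equal(compute_global_signal(run)$values, rep(0, 50),
               tolerance = 1e-12)

  run2 <- run_series(rbind(x, x, x), tr_s = 0.72)
  expect_equal(compute_global_signal(run2)$values, x, tolerance = 1e-12)

  withr::with_seed(2, m <- matrix(rnorm(100), 5, 20))
  oracle <- vapply(seq_len(20), function(j) {
    s <- 0
    for (i in 1:5) s <- s + m[i, j]
    s / 5
  }, numeric(1))
  expect_equal(compute_global_signal(run_series(m, 0.72))$values, oracle,
               tolerance = 1e-14)
})

test_that("edge truncation drops exactly n_edge frames per side", {
  fs <- frame_series(seq_len(1200), 0.72, "GS")
  tr <- truncate_series(fs, 10)
  expect_length(tr$values, 1180)
  expect_equal(tr$values[1], 11)
  expect_identical(truncate_series(fs, 0), fs)
  run <- run_series(matrix(rnorm(60), 3, 20), 0.72)
  expect_equal(ncol(truncate_series(run, 5)$bold), 10)
  expect_error(truncate_series(frame_series(1:10, 0.72), 10),
               "too short")
})

test_that("group lag search recovers a planted flipped shift", {
  n <- 400
  base <- smooth_series(n + 20, 3)
  gs <- frame_series(base[1:n], 0.72, "GS")
  # physio value at t - 16 equals -GS at t ("shifted backward by 16")
  physio <- frame_series(-base[17:(n + 16)], 0.72, "RVT")
  est <- estimate_group_lag(list(gs), list(physio))
  expect_equal(est$lag_frames, 16)
  expect_true(est$flip)
  expect_equal(est$lag_s, 16 * 0.72)

  ident <- estimate_group_lag(list(gs), list(gs))
  expect_equal(ident$lag_frames, 0)
  expect_false(ident$flip)

  # antisymmetry: swapping the two series negates the lag
  rev_est <- estimate_group_lag(list(physio), list(gs))
  expect_lte(abs(rev_est$lag_frames + est$lag_frames), 1)

  short <- frame_series(rnorm(50), 0.72)
  expect_error(estimate_group_lag(list(short), list(short)),
               "overlap")
})

test_that("individual lags are recovered per participant", {
  n <- 500
  lags <- c(14, 16, 18)
  for (i in seq_along(lags)) {
    base <- smooth_series(n + 30, 10 + i)
    gs <- frame_series(base[1:n], 0.72, "GS")
    ph <- frame_series(-base[(1 + lags[i]):(n + lags[i])], 0.72, "RVT")
    est <- estimate_individual_lag(list(gs), list(ph))
    expect_lte(abs(est$lag_frames - lags[i]), 1)
    expect_true(est$flip)
  }
  flat <- frame_series(rep(0, 500), 0.72)
  gs <- frame_series(smooth_series(500, 20), 0.72)
  expect_error(estimate_individual_lag(list(gs), list(flat)),
               "degenerate")
})

test_that("coupling maps Fisher-transform clipped correlations", {
  x <- smooth_series(200, 5)
  run <- run_series(rbind(roi_a = x, roi_b = -x), 0.72)
  topo <- compute_coupling_map(run, frame_series(x, 0.72))
  expect_equal(unname(topo$values["roi_a"]), atanh(1 - 1e-7))
  expect_equal(unname(topo$values["roi_b"]), -atanh(1 - 1e-7))

  # r = 0.5 maps to atanh(0.5) = 0.5493 (closed-form oracle)
  withr::with_seed(6, {
    a <- rnorm(5000)
    b <- 0.5 / sqrt(1 - 0.25) * a + rnorm(5000)
    b <- b / sd(b)
  })
  r_ab <- cor(a, b)
  topo2 <- compute_coupling_map(run_series(rbind(a), 0.72),
                                frame_series(b, 0.72))
  expect_equal(unname(topo2$values[1]), atanh(r_ab), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
})

test_that("coupling maps honor lag, flip, run averaging and rescaling", {
  n <- 300
  base <- smooth_series(n + 16, 7)
  ref <- frame_series(-base[17:(n + 16)], 0.72, "RVT")
  bold <- rbind(base[1:n] + 0.1 * rnorm(n), smooth_series(n, 8))
  run <- run_series(bold, 0.72)
  lag <- estimate_group_lag(list(frame_series(base[1:n], 0.72)),
                            list(ref))
  topo <- compute_coupling_map(run, ref, lag = lag)
  # after flip + shift the first ROI must correlate strongly
  expect_gt(topo$values[1], atanh(0.9))

  # run order must not matter
  run2 <- run_series(rbind(smooth_series(n, 9), smooth_series(n, 10)),
                     0.72)
  refs <- list(frame_series(smooth_series(n, 11), 0.72),
               frame_series(smooth_series(n, 12), 0.72))
  t12 <- compute_coupling_map(list(run, run2), refs)
  t21 <- compute_coupling_map(list(run2, run), rev(refs))
  expect_equal(t12$values, t21$values, tolerance = 1e-12)
  expect_equal(t12$n_runs_averaged, 2L)

  # correlation is invariant to per-ROI positive affine rescaling
  scaled <- run_series(run$bold * c(3.7, 0.2) + c(5, -2), 0.72)
  expect_equal(compute_coupling_map(scaled, ref, lag = lag)$values,
               topo$values, tolerance = 1e-9)

  # a zero-variance ROI becomes NA with a warning
  degen <- run_series(rbind(base[1:n], rep(1, n)), 0.72)
  expect_warning(t_na <- compute_coupling_map(degen,
                                              frame_series(base[1:n],
                                                           0.72)),
                 "zero variance")
  expect_true(is.na(t_na$values[2]))
})

test_that("GSCORR peaks at the ROI that dominates the global signal", {
  withr::with_seed(13, {
    s <- smooth_series(400, 14)
    noise <- matrix(rnorm(9 * 400, sd = 0.3), 9)
  })
  run <- run_series(rbind(10 * s, noise), 0.72)
  gs <- compute_global_signal(run)
  topo <- compute_coupling_map(run, gs)
  expect_equal(which.max(topo$values), 1L, ignore_attr = TRUE)
})
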