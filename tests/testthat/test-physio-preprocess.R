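make_breathing <- function(duration = 120, fs = 100, depth = 0.4,
                           noise = 0, seed = 1) {
  generate_respiratory_trace(duration, fs, mod_depth = depth,
                             noise_sd = noise, seed = seed)
}

test_that("respiratory cleaning standardizes and is gentle on clean input", {
  tr <- make_breathing(noise = 0.03)
  cl <- clean_respiratory_trace(tr)
  expect_equal(mean(cl$samples), 0, tolerance = 1e-9)
  expect_equal(sd(cl$samples), 1, tolerance = 1e-9)
  expect_identical(cl$state, "cleaned")

  # an already-clean unit-variance breathing signal passes nearly
  # unchanged (up to filter edge effects)
  pure <- make_breathing(noise = 0)
  z <- (pure$samples - mean(pure$samples)) / sd(pure$samples)
  cl2 <- clean_respiratory_trace(physio_trace(z, 100, "respiratory"))
  interior <- 500:11500
  expect_gt(cor(cl2$samples[interior], z[interior]), 0.999)

  expect_error(
    clean_respiratory_trace(physio_trace(rep(1, 2000), 100,
                                         "respiratory")),
    "zero-variance")
  expect_error(
    clean_respiratory_trace(physio_trace(rnorm(50), 100, "respiratory")),
    "warm-up")
})

test_that("a large spike is removed without disturbing the rest", {
  base <- make_breathing(noise = 0.02, seed = 3)
  spiked <- base
  mid <- length(base$samples) %/% 2
  spiked$samples[mid] <- spiked$samples[mid] + 50
  cl_base <- clean_respiratory_trace(base)
  cl_spiked <- clean_respiratory_trace(spiked)
  far <- abs(seq_along(base$samples) - mid) > 100  # outside 1 s at 100 Hz
  expect_lt(max(abs(cl_spiked$samples[far] - cl_base$samples[far])), 0.05)
})

test_that("cleaning is idempotent on the interior", {
  # narrowband input isolates the idempotence property from the filter's
  # (tiny) passband ripple across sidebands
  cl <- clean_respiratory_trace(make_breathing(depth = 0, noise = 0))
  again <- clean_respiratory_trace(
    physio_trace(cl$samples, cl$fs, "respiratory", "raw"))
  n <- length(cl$samples)
  interior <- round(0.05 * n):round(0.95 * n)
  expect_lt(max(abs(again$samples[interior] - cl$samples[interior])),
            1e-6)
})

test_that("RVT tracks the breathing envelope", {
  # constant amplitude A = 1: upper/lower envelopes at +/-A, so RVT ~ 2
  cl <- clean_respiratory_trace(make_breathing(depth = 0, noise = 0))
  # undo the final z-score's scaling to compare on the amplitude scale
  amp_scale <- sd(make_breathing(depth = 0, noise = 0)$samples)
  rvt <- derive_respiration_measure(cl, "rvt") * amp_scale
  inner <- 1000:11000  # away from the first/last breath cycles
  expect_lt(max(abs(rvt[inner] - 2) / 2), 0.05)

  # amplitude modulation: RVT tracks 2 * (1 + 0.5 sin(2 pi 0.03 t))
  am <- make_breathing(duration = 300, depth = 0.5, noise = 0)
  scl <- sd(am$samples)
  cl_am <- clean_respiratory_trace(am)
  rvt_am <- derive_respiration_measure(cl_am, "rvt") * scl
  t <- (seq_along(rvt_am) - 1) / 100
  expected <- 2 * (1 + 0.5 * sin(2 * pi * 0.03 * t))
  mid <- 3000:27000
  expect_lt(max(abs(rvt_am[mid] - expected[mid]) / expected[mid]), 0.05)

  # non-negative everywhere by construction
  noisy <- clean_respiratory_trace(make_breathing(noise = 0.1, seed = 9))
  expect_true(all(derive_respiration_measure(noisy, "rvt") >= 0))

  flat <- physio_trace(rnorm(2000, sd = 1e-3) +
                         sin(2 * pi * 0.01 * (1:2000) / 100), 100,
                       "respiratory", "cleaned")
  expect_error(derive_respiration_measure(flat, "rvt"), "3 breathing")
})

test_that("windowed RV matches the noise SD and ENV the amplitude", {
  withr::with_seed(11, {
    sigma <- 2
    noise <- physio_trace(rnorm(2e5, 0, sigma), 400, "respiratory",
                          "cleaned")
    rv <- derive_respiration_measure(noise, "rv")
    expect_lt(abs(mean(rv) - sigma) / sigma, 0.05)
  })
  cl <- clean_respiratory_trace(make_breathing(depth = 0, noise = 0))
  env <- derive_respiration_measure(cl, "env")
  inner <- 2000:10000
  expect_lt(max(abs(env[inner] - max(abs(cl$samples[inner])))), 0.1)
})

test_that("respiration measures are invariant to a sign flip", {
  cl <- clean_respiratory_trace(make_breathing(noise = 0.05, seed = 4))
  neg <- physio_trace(-cl$samples, cl$fs, "respiratory", "cleaned")
  for (m in c("rvt", "env", "rv"))
    expect_equal(derive_respiration_measure(cl, m),
                 derive_respiration_measure(neg, m), tolerance = 1e-10)
})

test_that("cardiac band-pass removes drift and mains noise by >= 20 dB", {
  ct <- generate_cardiac_trace(60, 400, mean_hr_bpm = 60, hr_sd_bpm = 0,
                               noise_sd = 0)
  t <- (seq_along(ct$samples) - 1) / 400
  amp_at <- function(x, f) {
    d <- lm.fit(cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1), x)
    sqrt(sum(coef(d)[1:2]^2))
  }
  for (f in c(0.05, 50)) {
    contaminated <- physio_trace(ct$samples + 3 * sin(2 * pi * f * t),
                                 400, "cardiac")
    cl <- clean_cardiac_trace(contaminated)
    # scale back to input units before comparing amplitudes
    raw_z <- (contaminated$samples - mean(contaminated$samples)) /
      sd(contaminated$samples)
    gain <- amp_at(cl$samples, f) / amp_at(raw_z, f)
    expect_lt(gain, 0.1)  # -20 dB
  }
})

test_that("instantaneous heart rate equals 60 / IBI", {
  metro <- generate_cardiac_trace(60, 400, mean_hr_bpm = 60,
                                  hr_sd_bpm = 0, noise_sd = 0)
  hr <- compute_heart_rate(clean_cardiac_trace(metro))
  expect_lt(max(abs(hr - 60)), 0.5)

  # alternating IBIs 0.75 / 0.85 s -> rates 80 and 60/0.85 bpm
  beats <- cumsum(c(0.5, rep(c(0.75, 0.85), 35)))
  fs <- 400
  n <- round(60 * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (b in beats) x <- x + exp(-0.5 * ((t - b) / 0.05)^2)
  hr2 <- compute_heart_rate(
    clean_cardiac_trace(physio_trace(x, fs, "cardiac")))
  mids <- round((beats[-1] + beats[-length(beats)]) / 2 * fs)
  rates <- hr2[mids]
  oracle <- 60 / rep(c(0.75, 0.85), 35)
  expect_lt(max(abs(rates - oracle)), 1)

  # output stays inside the physiological range even with a long gap
  gappy <- x
  gappy[round(20 * fs):round(30 * fs)] <- 0
  hr3 <- compute_heart_rate(
    clean_cardiac_trace(physio_trace(gappy, fs, "cardiac")))
  expect_true(all(hr3 >= 30 & hr3 <= 180))

  single <- physio_trace(exp(-0.5 * ((t - 30) / 0.05)^2), fs, "cardiac",
                         "cleaned")
  expect_error(compute_heart_rate(single), "fewer than 2")
})

test_that("frame resampling block-averages exactly", {
  out <- resample_to_frames(rep(3.5, 40 * 288), 400, 40, 0.72)
  expect_equal(out$values, rep(3.5, 40), tolerance = 1e-12)

  # linear ramp: each frame equals the arithmetic mean of its window,
  # (first + last) / 2 in closed form
  nfr <- 25
  spf <- 288  # 400 Hz * 0.72 s
  ramp <- seq(0, 1, length.out = nfr * spf)
  out2 <- resample_to_frames(ramp, 400, nfr, 0.72)
  expected <- vapply(seq_len(nfr), function(k)
    (ramp[(k - 1) * spf + 1] + ramp[k * spf]) / 2, numeric(1))
  expect_equal(out2$values, expected, tolerance = 1e-12)

  # the study grid consumes 1200 * 0.72 * 400 = 345,600 samples
  out3 <- resample_to_frames(rnorm(345600), 400, 1200, 0.72)
  expect_length(out3$values, 1200)
  expect_error(resample_to_frames(rnorm(345600 - 600), 400, 1200, 0.72),
               "too short")
})
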