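test_that("lowpass Butterworth has unit DC gain and -3.01 dB at cutoff", {
  # constant in -> constant out
  x <- signal_stream(rep(3.2, 500), fs = 100)
  for (ord in c(1, 2, 4)) {
    y <- butterworth_filter(x, filter_spec("lowpass", 10, order = ord))
    expect_equal(as.numeric(y$samples[1, 100:400]), rep(3.2, 301),
                 tolerance = 1e-6)
  }
  # |H| at the cutoff = 1/sqrt(2) for the Butterworth design
  bf <- signal::butter(2, 10 / 50, type = "low")
  w_c <- pi * 10 / 50
  Hc <- sum(bf$b * exp(-1i * w_c * (seq_along(bf$b) - 1))) /
    sum(bf$a * exp(-1i * w_c * (seq_along(bf$a) - 1)))
  expect_equal(20 * log10(Mod(Hc)), -3.0103, tolerance = 1e-3)
})

test_that("white-noise variance after lowpass matches frequency-domain integral", {
  set.seed(11)
  fs <- 1000
  x <- stats::rnorm(2e5)
  y <- butterworth_filter(
    signal_stream(x, fs), filter_spec("lowpass", 5, order = 2,
                                      mode = "online"))
  # oracle: numerical integral of |H(f)|^2 over the spectrum
  bf <- signal::butter(2, 5 / (fs / 2), type = "low")
  w <- seq(0, pi, length.out = 4096)
  H2 <- vapply(w, function(ww) Mod(
    sum(bf$b * exp(-1i * ww * (seq_along(bf$b) - 1))) /
      sum(bf$a * exp(-1i * ww * (seq_along(bf$a) - 1))))^2, numeric(1))
  expected_var <- stats::var(x) * mean(H2)
  got <- stats::var(as.numeric(y$samples[1, -(1:2000)]))  # drop transient
  expect_lt(abs(got - expected_var) / expected_var, 0.05)
})

test_that("filter specs are validated and designs are stable", {
  x <- signal_stream(stats::rnorm(100), fs = 100)
  expect_error(butterworth_filter(x, filter_spec("lowpass", 60)), "Nyquist")
  for (spec in list(filter_spec("lowpass", 8, order = 4),
                    filter_spec("bandpass", c(4, 12), order = 4),
                    filter_spec("highpass", 1, order = 2),
                    filter_spec("notch", notch_freq = 50))) {
    nyq <- 500
    filt <- if (spec$kind == "notch") {
      NULL
    } else {
      signal::butter(spec$order, spec$cutoff_hz / nyq,
                     type = switch(spec$kind, lowpass = "low",
                                   highpass = "high", bandpass = "pass"))
    }
    if (!is.null(filt)) {
      poles <- polyroot(rev(filt$a))
      expect_true(all(Mod(poles) < 1 + 1e-8))
    }
  }
})

test_that("EMG conditioning removes a pure 50 Hz tone and preserves modulation", {
  fs <- 1000
  tone <- sine_stream(50, fs = fs, dur = 3, modality = "emg")
  out <- emg_condition(tone)
  p_in <- mean(tone$samples^2)
  p_env <- mean(out$envelope$samples^2)
  expect_lt(p_env, 0.01 * p_in)
  # zero input -> zero envelope
  z <- signal_stream(rep(0, 3000), fs, modality = "emg")
  expect_equal(max(abs(emg_condition(z)$envelope$samples)), 0)
  expect_true(all(out$envelope$samples >= 0))
  # amplitude-modulated noise: envelope correlates with the modulator
  set.seed(12)
  tt <- seq(0, 5 - 1 / fs, by = 1 / fs)
  mod <- 0.5 + 0.5 * sin(2 * pi * 0.5 * tt)^2
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  carrier <- signal::filtfilt(bf, stats::rnorm(length(tt)))
  x <- signal_stream(carrier * mod, fs, modality = "emg")
  env <- emg_condition(x)$envelope$samples[1, ]
  expect_gt(stats::cor(env, mod), 0.9)
  expect_error(emg_condition(signal_stream(stats::rnorm(500), 500,
                                           modality = "emg")), ">= 900")
})

test_that("gyro integration matches closed forms", {
  fs <- 100
  const <- signal_stream(rep(10, 201), fs, modality = "imu_gyro",
                         channel_names = "gyro_y")
  th <- integrate_gyro(const)
  expect_equal(unname(th$samples[1, 201]), 20, tolerance = 1e-9)   # 10 deg/s x 2 s
  zero <- signal_stream(rep(0, 100), fs, modality = "imu_gyro",
                        channel_names = "gyro_y")
  expect_true(all(integrate_gyro(zero)$samples == 0))
  tt <- seq(0, 2, by = 1 / fs)
  cosw <- signal_stream(cos(tt), fs, modality = "imu_gyro",
                        channel_names = "gyro_y")
  expect_equal(as.numeric(integrate_gyro(cosw)$samples[1, ]), sin(tt),
               tolerance = 1e-4)   # trapezoid error O(dt^2)
})

test_that("lag estimation recovers integer shifts exactly and noisy shifts approximately", {
  set.seed(21)
  fs <- 100
  x <- as.numeric(stats::filter(stats::rnorm(600), rep(0.2, 5), sides = 2))
  x[is.na(x)] <- 0
  expect_equal(estimate_lag(x, x, fs = fs), 0)
  # exhaustive noiseless integer shifts
  for (k in c(-20, -7, -1, 1, 5, 20)) {
    y <- if (k > 0) c(rep(0, k), x[1:(600 - k)]) else c(x[(1 - k):600], rep(0, -k))
    expect_equal(estimate_lag(x, y, max_lag = 0.3, fs = fs), k / fs)
  }
  # 5-sample delay at 100 Hz = 50 ms
  y5 <- c(rep(0, 5), x[1:595])
  expect_equal(estimate_lag(x, y5, fs = fs), 0.05)
  # SNR 10 dB noise: within 10 ms over 20 seeds
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    sig_sd <- stats::sd(x)
    noise <- stats::rnorm(600, 0, sig_sd / sqrt(10))
    abs(estimate_lag(x, y5 + noise, fs = fs) - 0.05)
  }, numeric(1))
  expect_true(all(errs <= 0.010 + 1e-12))
  expect_error(estimate_lag(rep(1, 100), x[1:100], fs = fs), "constant")
})

test_that("resampling preserves ramps, steps and band-limited content", {
  fs_hi <- 1000
  tt <- seq(0, 2 - 1 / fs_hi, by = 1 / fs_hi)
  ramp <- signal_stream(3 * tt, fs_hi)
  out <- resample_align(list(r = ramp), target_fs = 100)$r
  expect_equal(as.numeric(out$samples[1, ]), 3 * stream_time(out),
               tolerance = 1e-9)
  # ZOH keeps a step a step
  step <- signal_stream(as.numeric(tt >= 1), fs_hi)
  z <- resample_align(list(s = step), target_fs = 100, method = "zoh")$s
  vals <- unique(as.numeric(z$samples))
  expect_true(all(vals %in% c(0, 1)))
  edge <- which(diff(as.numeric(z$samples[1, ])) == 1)
  expect_lte(abs(stream_time(z)[edge + 1] - 1), 1 / 100 + 1e-9)
  # round trip 100 -> 1000 -> 100 Hz of a 5 Hz sinusoid
  fs_lo <- 100
  t_lo <- seq(0, 2 - 1 / fs_lo, by = 1 / fs_lo)
  s <- signal_stream(sin(2 * pi * 5 * t_lo), fs_lo)
  up <- resample_align(list(x = s), target_fs = 1000)$x
  down <- resample_align(list(x = up), target_fs = 100)$x
  m <- min(ncol(down$samples), length(t_lo))
  truth <- sin(2 * pi * 5 * t_lo[1:m])
  rmse <- sqrt(mean((down$samples[1, 1:m] - truth)^2))
  expect_lt(rmse / sqrt(mean(truth^2)), 0.01)
  expect_error(resample_align(list(
    a = signal_stream(1:10, 10, t0 = 0),
    b = signal_stream(1:10, 10, t0 = 100))), "overlapping")
})

test_that("Hampel cleaning replaces spikes, is idempotent, and scores quality", {
  fs <- 100
  tt <- seq(0, 5, by = 1 / fs)
  clean <- signal_stream(sin(2 * pi * tt), fs)
  res <- hampel_clean(clean)
  expect_equal(res$Q, 1)
  expect_equal(res$stream$samples, clean$samples)
  # single 100x spike is exactly the replaced sample
  spiky <- clean
  spiky$samples[1, 250] <- 100
  res2 <- hampel_clean(spiky)
  expect_true(res2$mask[1, 250])
  expect_equal(sum(res2$mask), 1)
  expect_lt(abs(res2$stream$samples[1, 250] - sin(2 * pi * tt[250])), 0.2)
  # 5% injected spikes: >= 95% detected, < 1% false positives
  set.seed(31)
  x <- sine_stream(2, fs = 100, dur = 10)
  n <- ncol(x$samples)
  spikes <- sample(seq(10, n - 10), round(0.05 * n))
  x$samples[1, spikes] <- x$samples[1, spikes] + 30 * sample(c(-1, 1), length(spikes), TRUE)
  res3 <- hampel_clean(x)
  hit <- mean(spikes %in% which(res3$mask[1, ]))
  fp <- sum(res3$mask[1, -spikes]) / (n - length(spikes))
  expect_gte(hit, 0.95)
  expect_lt(fp, 0.01)
  # idempotence
  res4 <- hampel_clean(res3$stream)
  expect_equal(res4$stream$samples, res3$stream$samples, tolerance = 1e-12)
  # short gaps interpolated and masked
  g <- clean
  g$samples[1, 100:104] <- NA
  resg <- hampel_clean(g)
  expect_false(any(is.na(resg$stream$samples)))
  expect_true(all(resg$mask[1, 100:104]))
  expect_lt(resg$Q, 1)
})

test_that("TKEO identities and burst onset detection", {
  # constant signal: psi == 0, no onsets
  expect_true(all(tkeo(rep(2.5, 100)) == 0))
  # sinusoid: psi ~ A^2 sin^2(omega), constant
  A <- 3; om <- 0.3
  x <- A * sin(om * (1:500))
  psi <- tkeo(x)[5:495]
  expect_equal(psi, rep(A^2 * sin(om)^2, length(psi)), tolerance = 1e-9)
  expect_error(tkeo(c(1, 2)), "3 samples")
  # burst at t = 2.0 s detected within 50 ms
  set.seed(41)
  fs <- 1000
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- stats::rnorm(length(tt), 0, 0.1)
  x[tt >= 2] <- x[tt >= 2] * 10
  onsets <- tkeo_onset(signal_stream(x, fs))
  expect_gte(length(onsets), 1)
  expect_lt(abs(onsets[1] - 2.0), 0.05)
})

test_that("segmentation and windowing count and coverage contracts hold", {
  fs <- 100
  x <- signal_stream(stats::rnorm(1500), fs)
  tr <- list(trial_spec(1, t_start = 2, t_end = 12, distance_D = 30,
                        width_W = 10))
  segs <- segment_and_window(x, tr, window_ms = 200, overlap = 0.5)
  expect_equal(nrow(segs[[1]]$windows), 99)   # floor((1000-20)/10)+1
  segs0 <- segment_and_window(x, tr, window_ms = 200, overlap = 0)
  expect_equal(nrow(segs0[[1]]$windows), 50)
  # windows never cross segment boundaries (randomized logs)
  set.seed(51)
  for (r in 1:20) {
    t0 <- stats::runif(1, 0, 5)
    t1 <- t0 + stats::runif(1, 0.5, 8)
    ss <- segment_and_window(x, list(trial_spec(1, t0, t1, 30, 10)),
                             window_ms = 200,
                             overlap = sample(c(0, 0.25, 0.5, 0.75), 1))
    w <- ss[[1]]$windows
    if (nrow(w)) {
      expect_true(all(w$start_idx >= ss[[1]]$start_idx))
      expect_true(all(w$end_idx <= ss[[1]]$end_idx))
    }
    # coverage: union of windows reaches within one window of the segment end
    if (nrow(w)) {
      wlen <- w$end_idx[1] - w$start_idx[1]
      expect_lte(ss[[1]]$end_idx - max(w$end_idx), wlen)
    }
  }
  expect_warning(
    segment_and_window(x, list(trial_spec(1, 2, 2.05, 30, 10))),
    "shorter")
})
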