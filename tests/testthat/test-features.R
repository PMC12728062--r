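# independent brute-force SPARC: direct DFT arc length, no shared code path
brute_sparc <- function(v, fs, fc = 20, amp_th = 0.05, padlevel = 4) {
  nfft <- 2^(ceiling(log2(length(v))) + padlevel)
  vv <- c(v, rep(0, nfft - length(v)))
  k <- 0:(nfft / 2)
  M <- vapply(k, function(kk)
    Mod(sum(vv * exp(-2i * pi * kk * (seq_along(vv) - 1) / nfft))), numeric(1))
  f <- k * fs / nfft
  M <- M / M[1]
  keep <- f <= fc
  f <- f[keep]; M <- M[keep]
  ab <- which(M >= amp_th)
  sel <- ab[1]:ab[length(ab)]
  f <- f[sel]; M <- M[sel]
  -sum(sqrt((diff(f) / (f[length(f)] - f[1]))^2 + diff(M)^2))
}

brute_ldlj <- function(theta, fs) {
  dt <- 1 / fs
  v <- diff(theta) / dt
  j <- diff(diff(diff(theta))) / dt^3
  -log((length(theta) * dt)^5 / max(abs(v))^2 * sum(j^2) * dt)
}

min_jerk_reach <- function(fs = 100, T = 2, A = 40) {
  tau <- seq(0, 1, length.out = fs * T)
  A * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

test_that("ROM arithmetic and kinematic feature contracts", {
  th <- c(10, 45, 30)
  kf <- kinematic_features(c(th, 20, 25), fs = 10, rom_base = 70)
  expect_equal(unname(kf["ROM"]), 35)
  expect_equal(unname(kf["ROMn"]), 0.5)
  expect_error(kinematic_features(min_jerk_reach(), 100, rom_base = 0),
               "rom_base")
})

test_that("SPARC and LDLJ match independent brute-force implementations on a minimum-jerk reach", {
  th <- min_jerk_reach()
  v <- abs(diff(th) * 100)
  expect_equal(sparc(v, 100), brute_sparc(v, 100), tolerance = 1e-6)
  expect_equal(ldlj(th, 100), brute_ldlj(th, 100), tolerance = 1e-6)
})

test_that("LDLJ is invariant under amplitude scaling", {
  th <- min_jerk_reach()
  expect_equal(ldlj(th, 100), ldlj(5.7 * th, 100), tolerance = 1e-9)
})

test_that("smoothness metrics degrade monotonically with jitter amplitude", {
  th <- min_jerk_reach()
  amps <- seq(0, 2, length.out = 11)[-1]
  med_sparc <- med_ldlj <- matrix(NA, 20, length(amps))
  for (s in 1:20) {
    set.seed(70 + s)
    jit <- stats::rnorm(length(th))
    for (a in seq_along(amps)) {
      noisy <- th + amps[a] * jit
      med_sparc[s, a] <- sparc(abs(diff(noisy) * 100), 100)
      med_ldlj[s, a] <- ldlj(noisy, 100)
    }
  }
  ms <- colMeans(med_sparc)
  ml <- colMeans(med_ldlj)
  expect_true(all(diff(ms) < 0))
  expect_true(all(diff(ml) < 0))
  expect_lt(ms[1], sparc(abs(diff(th) * 100), 100))
})

test_that("assistive energy integrals match closed forms", {
  fs <- 1000
  n <- 2 * fs + 1
  expect_equal(assist_energy(rep(1, n), rep(1, n), fs = fs), 2,
               tolerance = 1e-9)
  expect_equal(assist_energy(rep(1, n), rep(0, n), fs = fs), 0)
  tt <- seq(0, 2, by = 1 / fs)   # quadrature over full periods
  expect_equal(assist_energy(sin(2 * pi * tt), cos(2 * pi * tt), fs = fs), 0,
               tolerance = 1e-6)
})

test_that("EMG time-domain features match hand values", {
  f <- emg_time_features(rep(2.5, 50))
  expect_equal(unname(f[c("RMS", "MAV", "WL", "ZC")]), c(2.5, 2.5, 0, 0))
  expect_equal(unname(emg_time_features(c(3, 4))["RMS"]), sqrt(12.5))
  alt <- rep(c(1, -1), 25)
  expect_equal(unname(emg_time_features(alt)["ZC"]), 49)   # N - 1 crossings
  # deadband suppresses sub-threshold crossings
  tiny <- rep(c(0.01, -0.01), 25)
  expect_equal(unname(emg_time_features(tiny, deadband = 0.1)["ZC"]), 0)
})

test_that("spectral features: tone, symmetry and flat-band oracle", {
  fs <- 1000
  tone <- as.numeric(sine_stream(100, fs = fs, dur = 1)$samples)
  f <- emg_freq_features(tone, fs)
  expect_equal(unname(f["MNF"]), 100, tolerance = 3)
  expect_equal(unname(f["MDF"]), 100, tolerance = fs / 128)
  # spectrum symmetric about f0: MNF = f0
  two <- as.numeric(sine_stream(80, fs = fs, dur = 1)$samples) +
    as.numeric(sine_stream(120, fs = fs, dur = 1)$samples)
  expect_equal(unname(emg_freq_features(two, fs)["MNF"]), 100, tolerance = 3)
  # band-limited white noise 20-450 Hz: MNF ~ (450^2-20^2)/(2*(450-20)) = 235
  set.seed(81)
  bf <- signal::butter(6, c(20, 450) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(2e5))
  expect_equal(unname(emg_freq_features(x, fs)["MNF"]),
               (450^2 - 20^2) / (2 * (450 - 20)), tolerance = 0.05 * 235)
  expect_true(all(is.na(emg_freq_features(rep(0, 200), fs))))
  expect_error(emg_freq_features(1:10, fs), "64")
})

test_that("co-contraction index identities, symmetry and scale invariance", {
  expect_equal(cci(c(1, 2), c(2, 1)), 0.5)
  e <- c(0.5, 1, 0.2)
  expect_equal(cci(e, e), 1)
  expect_equal(cci(c(1, 0), c(0, 1)), 0)
  set.seed(91)
  a <- stats::runif(50); b <- stats::runif(50)
  expect_equal(cci(a, b), cci(b, a))
  expect_equal(cci(3.7 * a, 3.7 * b), cci(a, b), tolerance = 1e-12)
  expect_error(cci(c(-1, 1), c(1, 1)), "non-negative")
  expect_true(is.na(cci(c(0, 0), c(0, 0))))
})

test_that("electromechanical delay arithmetic and construction oracle", {
  expect_equal(emd_delay(0.5, 0.5), 0)
  expect_equal(emd_delay(0.10, 0.16), 0.06)
  expect_true(is.na(emd_delay(NA, 0.2)))
  expect_warning(emd_delay(0.3, 0.2), "negative")
  # synthetic segment with built-in 60 ms lag between EMG and motion bursts
  set.seed(92)
  fs <- 1000
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  burst <- function(t_on) {
    x <- stats::rnorm(length(tt), 0, 0.05)
    x[tt >= t_on] <- x[tt >= t_on] * 12
    signal_stream(x, fs)
  }
  e_on <- tkeo_onset(burst(1.00))[1]
  m_on <- tkeo_onset(burst(1.06))[1]
  expect_equal(emd_delay(e_on, m_on), 0.06, tolerance = 0.02)
})

test_that("mutual information: independence, discrete identity and Gaussian closed form", {
  set.seed(101)
  x <- stats::runif(10000); y <- stats::runif(10000)
  expect_lte(mutual_info(x, y), 0.05)
  lv <- rep(0:3, each = 5000)  # exactly equiprobable levels
  expect_equal(mutual_info(lv, lv), 2, tolerance = 1e-9)
  # bivariate Gaussian rho = 0.9: MI = -0.5 log2(1 - 0.81) ~ 1.198 bits
  rho <- 0.9
  z1 <- stats::rnorm(50000)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(50000)
  expect_equal(mutual_info(z1, z2), -0.5 * log2(1 - rho^2),
               tolerance = 0.15 * 1.198)
  expect_warning(mi0 <- mutual_info(rep(1, 200), stats::rnorm(200)),
                 "constant")
  expect_equal(mi0, 0)
})

test_that("Fitts difficulty and throughput identities and monotonicity", {
  tr <- function(D, W, T) trial_spec(1, 0, T, D, W, success = TRUE)
  expect_equal(task_features(list(tr(10, 10, 1)))$aggregate[["fitts_ID"]], 1)
  expect_equal(task_features(list(tr(30, 10, 1)))$aggregate[["fitts_ID"]], 2)
  expect_equal(task_features(list(tr(30, 10, 0.5)))$aggregate[["fitts_TP"]], 4)
  # ID strictly increasing in D, decreasing in W
  ids_D <- vapply(seq(5, 50, by = 5), function(D)
    task_features(list(tr(D, 10, 1)))$aggregate[["fitts_ID"]], numeric(1))
  ids_W <- vapply(seq(2, 20, by = 2), function(W)
    task_features(list(tr(30, W, 1)))$aggregate[["fitts_ID"]], numeric(1))
  expect_true(all(diff(ids_D) > 0))
  expect_true(all(diff(ids_W) < 0))
  expect_error(task_features(list()), "non-empty")
})

test_that("normalization modes, EMA recursion and round trips", {
  set.seed(111)
  X <- matrix(stats::rnorm(200), 50, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  ref <- fit_baseline(X, alpha = 0.05)
  x <- c(a = 1, b = -0.5, c = 2, d = 0)
  for (mode in c("zscore", "ratio", "robust")) {
    z <- normalize_features(x, ref, mode)
    back <- denormalize_features(z, ref, mode)
    expect_equal(unname(back), unname(x), tolerance = 1e-12)
  }
  # alpha = 1: EMA equals the new observation
  ref1 <- fit_baseline(X, alpha = 1)
  expect_equal(unname(ema_update(ref1, x)$ema["a"]), 1)
  # geometric approach to a constant input
  refc <- fit_baseline(X, alpha = 0.05)
  refc$ema[] <- 0
  r <- refc
  for (t in 1:30) r <- ema_update(r, c(a = 2, b = 2, c = 2, d = 2))
  expect_equal(unname(abs(r$ema["a"] - 2)), (1 - 0.05)^30 * 2,
               tolerance = 1e-9)
  # three-step hand recursion oracle (alpha = 0.05, x = 1,2,3, mu0 = 0)
  oracle <- Reduce(function(mu, x) 0.05 * x + 0.95 * mu, c(1, 2, 3),
                   accumulate = FALSE, init = 0)
  r3 <- refc
  for (x_t in c(1, 2, 3)) r3 <- ema_update(r3, c(a = x_t, b = 0, c = 0, d = 0))
  expect_equal(unname(r3$ema["a"]), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.290125)
})

test_that("feature selection: variance filter, duplicate pruning, PCA retention", {
  set.seed(121)
  n <- 300
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  X <- cbind(f1 = x1, f2 = x2, f3 = x1 + stats::rnorm(n, 0, 1e-4),
             f4 = rep(1, n), f5 = stats::rnorm(n))
  y <- x1 + 0.5 * x2
  sel <- select_features(X, y, budget = 3, mode = "online")
  expect_true(1 %in% sel)            # informative feature kept
  expect_false(all(c(1, 3) %in% sel))  # duplicated column pruned
  expect_false(4 %in% sel)           # zero-variance dropped
  # constructed covariance: two strong directions + 1% noise third
  A <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0.1))
  Z <- matrix(stats::rnorm(3 * 2000), 2000, 3) %*% t(A)
  colnames(Z) <- c("p", "q", "r")
  pc <- select_features(Z, mode = "offline", var_retain = 0.95)
  expect_equal(pc$n_components, 2)
  expect_error(select_features(X, y, budget = 0), "budget")
  # label-independent data: selection deterministic via index-order tie-break
  y0 <- stats::rnorm(n)
  s1 <- select_features(X, y0, budget = 3)
  s2 <- select_features(X, y0, budget = 3)
  expect_identical(s1, s2)
})
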