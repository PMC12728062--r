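#' Virtual patient definition
#'
#' Latent parameters of a simulated rehabilitation patient. `capability` is
#' the unitless motor capability in [0, 1] that drives range of motion, trial
#' success and the response to assistance; `rom_base` is the individually
#' calibrated baseline range of motion used for ROM normalization.
#'
#' @param capability latent motor capability in `[0, 1]`.
#' @param rom_base calibrated baseline range of motion, degrees (> 0).
#' @param tremor_amp amplitude of 4-12 Hz tremor, degrees.
#' @param cocontraction antagonist coupling in `[0, 1]`.
#' @param noise_sd performance noise standard deviation (unitless).
#' @param learn_rate per-session capability gain.
#' @param anchors named list with clinical anchors `fma_0`, `fma_T`
#'   (Fugl-Meyer upper extremity, 0-66) and optionally `arat_0`, `arat_T`
#'   (Action Research Arm Test, 0-57).
#'
#' @return object of class `virtual_patient`.
#' @export
virtual_patient <- function(capability = 0.5, rom_base = 60,
                            tremor_amp = 0, cocontraction = 0.2,
                            noise_sd = 0.05, learn_rate = 0.02,
                            anchors = list(fma_0 = 30, fma_T = 39,
                                           arat_0 = 20, arat_T = 28)) {
  stopifnot(capability >= 0, capability <= 1,
            cocontraction >= 0, cocontraction <= 1,
            rom_base > 0, tremor_amp >= 0, noise_sd >= 0)
  if (anchors$fma_0 < 0 || anchors$fma_0 > 66 ||
      anchors$fma_T < 0 || anchors$fma_T > 66)
    stop("FMA-UE anchors must lie in [0, 66]")
  if (!is.null(anchors$arat_0) &&
      (anchors$arat_0 < 0 || anchors$arat_0 > 57 ||
       anchors$arat_T < 0 || anchors$arat_T > 57))
    stop("ARAT anchors must lie in [0, 57]")
  structure(list(capability = capability, rom_base = rom_base,
                 tremor_amp = tremor_amp, cocontraction = cocontraction,
                 noise_sd = noise_sd, learn_rate = learn_rate,
                 anchors = anchors),
            class = "virtual_patient")
}

#' Fitts-style trial specification
#'
#' @param trial_id integer id.
#' @param t_start,t_end trial start/end times, seconds.
#' @param distance_D target distance, cm (> 0).
#' @param width_W target width, cm (> 0).
#' @param success logical trial outcome (may be NA before simulation).
#' @return object of class `trial_spec` (a one-row list).
#' @export
trial_spec <- function(trial_id, t_start, t_end, distance_D, width_W,
                       success = NA) {
  stopifnot(distance_D > 0, width_W > 0, t_end > t_start)
  structure(list(trial_id = trial_id, t_start = t_start, t_end = t_end,
                 distance_D = distance_D, width_W = width_W,
                 duration_T = t_end - t_start, success = success),
            class = "trial_spec")
}

#' Course configuration
#'
#' Defaults mirror a 4-week programme: 20 sessions with 15-20 reach-grasp
#' trials each and 200 ms analysis windows.
#'
#' @param n_sessions number of sessions (default 20).
#' @param trials_per_session trials per session (default 16).
#' @param window_ms analysis window length in ms (default 200).
#' @param trial_duration_s nominal trial duration, seconds.
#' @param gap_s inter-trial rest gap, seconds.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return object of class `course_config`.
#' @export
course_config <- function(n_sessions = 20, trials_per_session = 16,
                          window_ms = 200, trial_duration_s = 6,
                          gap_s = 2, seed = 1L) {
  stopifnot(n_sessions >= 1, trials_per_session >= 1, window_ms > 0,
            trial_duration_s > 0, gap_s >= 0)
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 window_ms = window_ms, trial_duration_s = trial_duration_s,
                 gap_s = gap_s, seed = as.integer(seed)),
            class = "course_config")
}

#' Generate a block of trials on a session timeline
#'
#' Target geometry follows the VR difficulty mapping: difficulty `d` in
#' [0, 1] maps linearly to target width 15 -> 5 cm and distance 20 -> 50 cm,
#' so the Fitts index of difficulty rises with `d`.
#'
#' @param n number of trials.
#' @param difficulty scalar difficulty in `[0, 1]`.
#' @param duration_s nominal trial duration, seconds (jittered +-20%).
#' @param gap_s rest gap between trials, seconds.
#' @param t0 session start time, seconds.
#' @return list of `trial_spec`.
#' @export
make_trials <- function(n, difficulty = 0.3, duration_s = 6, gap_s = 2,
                        t0 = 0) {
  stopifnot(n >= 1, difficulty >= 0, difficulty <= 1)
  W <- 15 - 10 * difficulty
  D <- 20 + 30 * difficulty
  out <- vector("list", n)
  t <- t0
  for (i in seq_len(n)) {
    Ti <- duration_s * stats::runif(1, 0.8, 1.2)
    out[[i]] <- trial_spec(i, t, t + Ti, distance_D = D, width_W = W)
    t <- t + Ti + gap_s
  }
  out
}

# Minimum-jerk position profile on normalized time tau in [0,1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Ground-truth joint angle (deg) over a session timeline: rest at 0, one
# reach (0 -> amp) for 40% of each trial, hold, return (amp -> 0) for the
# final 40%. Peak-to-peak excursion equals `amp` exactly.
session_angle <- function(tt, trials, amp) {
  theta <- numeric(length(tt))
  for (tr in trials) {
    T <- tr$t_end - tr$t_start
    rel <- (tt - tr$t_start) / T
    inside <- rel >= 0 & rel < 1
    r <- rel[inside]
    seg <- ifelse(r < 0.4, min_jerk(r / 0.4),
                  ifelse(r < 0.6, 1, 1 - min_jerk((r - 0.6) / 0.4)))
    theta[inside] <- amp * seg
  }
  theta
}

# Trapezoid-consistent discrete derivative: cumulative trapezoidal
# integration of the returned rate reproduces `theta` exactly.
trapz_consistent_rate <- function(theta, fs) {
  n <- length(theta)
  w <- numeric(n)
  if (n < 2) return(w)
  d <- diff(theta) * fs * 2
  for (k in 2:n) w[k] <- d[k - 1] - w[k - 1]
  w
}

# Band-limited noise via 4th-order Butterworth bandpass, scaled to a target
# peak amplitude.
bandlimited_noise <- function(n, fs, low, high, amp, order = 4) {
  x <- stats::rnorm(n)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  if (max(abs(y)) > 0) y <- y / max(abs(y)) * amp
  y
}

#' Generate a synthetic IMU stream for a set of trials
#'
#' Builds a minimum-jerk reach-grasp-release joint-angle trajectory whose
#' excursion is `capability * rom_base`, adds band-limited 4-12 Hz tremor of
#' amplitude `tremor_amp`, and emits gyroscope (deg/s) and accelerometer
#' (m/s^2, gravity tilt for a single pitch axis) channels with additive
#' sensor noise. The gyro pitch channel is the trapezoid-consistent discrete
#' derivative of the underlying angle, so [integrate_gyro()] recovers the
#' angle to machine precision in the noise-free case. The ground-truth angle
#' is attached as attribute `"angle"` (a `signal_stream`).
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param patient a [virtual_patient()].
#' @param trials non-empty list of [trial_spec()].
#' @param fs sampling rate in Hz, >= 50.
#' @param gyro_noise_sd gyro sensor noise SD, deg/s (scaled by
#'   `patient$noise_sd`).
#' @param accel_noise_sd accelerometer noise SD, m/s^2 (scaled likewise).
#' @return a `signal_stream` with channels `gyro_x, gyro_y, gyro_z,
#'   accel_x, accel_y, accel_z`.
#' @export
gen_imu_stream <- function(patient, trials, fs = 100,
                           gyro_noise_sd = 1.0, accel_noise_sd = 0.05) {
  stopifnot(inherits(patient, "virtual_patient"))
  if (length(trials) == 0) stop("trial list must be non-empty")
  if (fs < 50) stop("fs must be >= 50 Hz")
  t_end <- max(vapply(trials, function(tr) tr$t_end, numeric(1))) + 1
  t0 <- min(vapply(trials, function(tr) tr$t_start, numeric(1)))
  tt <- seq(t0, t_end, by = 1 / fs)
  amp <- patient$capability * patient$rom_base
  theta <- session_angle(tt, trials, amp)
  if (patient$tremor_amp > 0) {
    if (fs < 24) {
      warning("fs below tremor Nyquist (24 Hz); tremor omitted")
    } else {
      theta <- theta + bandlimited_noise(length(tt), fs, 4, 12,
                                         patient$tremor_amp)
    }
  }
  omega <- trapz_consistent_rate(theta, fs)
  nsd <- patient$noise_sd
  g <- 9.81
  th_rad <- theta * pi / 180
  samples <- rbind(
    gyro_x  = stats::rnorm(length(tt), 0, gyro_noise_sd * nsd),
    gyro_y  = omega + stats::rnorm(length(tt), 0, gyro_noise_sd * nsd),
    gyro_z  = stats::rnorm(length(tt), 0, gyro_noise_sd * nsd),
    accel_x = -g * sin(th_rad) + stats::rnorm(length(tt), 0, accel_noise_sd * nsd),
    accel_y = stats::rnorm(length(tt), 0, accel_noise_sd * nsd),
    accel_z = g * cos(th_rad) + stats::rnorm(length(tt), 0, accel_noise_sd * nsd)
  )
  out <- signal_stream(samples, fs, t0 = t0, modality = "imu_gyro",
                       channel_names = rownames(samples),
                       units = "deg/s | m/s^2")
  attr(out, "angle") <- signal_stream(theta, fs, t0 = t0, modality = "angle",
                                      channel_names = "pitch", units = "deg")
  out
}

# Smooth per-trial activation envelope (raised cosine over the movement
# phases), on [0, 1].
activation_envelope <- function(tt, trials) {
  env <- numeric(length(tt))
  for (tr in trials) {
    T <- tr$t_end - tr$t_start
    rel <- (tt - tr$t_start) / T
    inside <- rel >= 0 & rel < 1
    env[inside] <- pmax(env[inside], sin(pi * rel[inside])^2)
  }
  env
}

#' Generate a synthetic multichannel sEMG stream
#'
#' Each channel is Gaussian noise band-limited to 20-450 Hz, amplitude
#' modulated by an activation envelope synchronized to the trial phases.
#' Odd-indexed channels are agonists; even-indexed channels receive the
#' agonist envelope scaled by `patient$cocontraction` (antagonists). A line
#' interference component at `line_hz` can be added. The noise-free agonist
#' and antagonist envelopes are attached as attribute `"envelopes"`.
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param patient a [virtual_patient()].
#' @param trials non-empty list of [trial_spec()].
#' @param fs sampling rate in Hz; 1000 Hz recommended.
#' @param n_channels number of channels (>= 2 when cocontraction > 0).
#' @param line_amp amplitude of the mains interference component (same
#'   arbitrary units as the EMG; 0 disables).
#' @param line_hz mains frequency, default 50 Hz.
#' @param baseline_level resting noise floor as a fraction of the active
#'   modulation amplitude.
#' @return a `signal_stream` with modality `"emg"`.
#' @export
gen_emg_stream <- function(patient, trials, fs = 1000, n_channels = 2,
                           line_amp = 0, line_hz = 50,
                           baseline_level = 0.05) {
  stopifnot(inherits(patient, "virtual_patient"))
  if (length(trials) == 0) stop("trial list must be non-empty")
  if (n_channels < 2 && patient$cocontraction > 0)
    stop("need >= 2 channels to model antagonist co-contraction")
  t_end <- max(vapply(trials, function(tr) tr$t_end, numeric(1))) + 1
  t0 <- min(vapply(trials, function(tr) tr$t_start, numeric(1)))
  tt <- seq(t0, t_end, by = 1 / fs)
  n <- length(tt)
  env_a <- activation_envelope(tt, trials)
  env_b <- env_a * patient$cocontraction
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  samples <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    carrier <- signal::filtfilt(bf, stats::rnorm(n))
    env <- if (ch %% 2 == 1) env_a else env_b
    x <- carrier * (baseline_level + env)
    if (line_amp > 0)
      x <- x + line_amp * sin(2 * pi * line_hz * (tt - t0))
    samples[ch, ] <- x
  }
  out <- signal_stream(samples, fs, t0 = t0, modality = "emg", units = "a.u.")
  attr(out, "envelopes") <- list(agonist = env_a, antagonist = env_b)
  out
}

#' Virtual-patient performance response
#'
#' Instantaneous true performance of a patient given capability `c`,
#' assistance `u` and difficulty `d`:
#' `S = clip(sigmoid(b0 + b1*c + b2*u - b3*d) + eps, 0, 1)` with
#' `eps ~ N(0, noise_sd)`. The default coefficients place the assistance
#' fixed point for the target score inside the admissible range for a
#' mid-capability patient.
#'
#' @param patient a [virtual_patient()].
#' @param u assistance level in `[0, 1]`.
#' @param d difficulty in `[0, 1]`.
#' @param beta coefficients `c(b0, b1, b2, b3)`.
#' @param noisy add the Gaussian performance noise (default TRUE).
#' @return scalar performance in `[0, 1]`.
#' @export
patient_response <- function(patient, u, d,
                             beta = c(-1.0, 2.0, 1.0, 1.2), noisy = TRUE) {
  s <- stats::plogis(beta[1] + beta[2] * patient$capability +
                       beta[3] * u - beta[4] * d)
  if (noisy && patient$noise_sd > 0)
    s <- s + stats::rnorm(length(s), 0, patient$noise_sd)
  pmin(pmax(s, 0), 1)
}

#' Reference improving virtual patient
#'
#' The moderately-to-severely impaired improving patient used as the
#' standard condition for closed-loop course simulations: baseline
#' capability 0.25, trial-to-trial performance noise 0.15, per-session
#' learning rate 0.08, clinical anchors FMA-UE 26 -> 37.
#'
#' @param capability,noise_sd,learn_rate overrides of the reference values.
#' @return a [virtual_patient()].
#' @export
improving_patient <- function(capability = 0.25, noise_sd = 0.15,
                              learn_rate = 0.08) {
  virtual_patient(capability = capability, noise_sd = noise_sd,
                  learn_rate = learn_rate,
                  anchors = list(fma_0 = 26, fma_T = 37,
                                 arat_0 = 16, arat_T = 24))
}

#' Generate a longitudinal training course
#'
#' Produces one signal bundle per session (IMU + sEMG streams and trial
#' logs) for a patient whose capability improves linearly:
#' `c_{s+1} = clip(c_s + learn_rate, 0, 1)`. Clinical anchors are attached
#' at the first and last session. Trial success uses the rule
#' `patient_response >= 0.5` at a fixed nominal assistance/difficulty.
#'
#' @param patient a [virtual_patient()].
#' @param config a [course_config()].
#' @param fs_imu,fs_emg sampling rates for the generated streams.
#' @param difficulty nominal session difficulty used for trial geometry.
#' @param assistance nominal assistance used by the success rule.
#' @param modalities which signal modalities to synthesize (subset of
#'   `c("imu", "emg")`); dropping one speeds up large Monte-Carlo studies.
#' @return object of class `course_record`: list with `sessions` (each with
#'   `capability`, `trials`, `imu`, `emg`), `anchors`, `config`.
#' @export
gen_course <- function(patient, config = course_config(),
                       fs_imu = 100, fs_emg = 1000,
                       difficulty = 0.3, assistance = 0.6,
                       modalities = c("imu", "emg")) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(config, "course_config"))
  set.seed(config$seed)
  cap <- patient$capability
  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    p_s <- patient
    p_s$capability <- cap
    trials <- make_trials(config$trials_per_session, difficulty,
                          duration_s = config$trial_duration_s,
                          gap_s = config$gap_s)
    for (i in seq_along(trials))
      trials[[i]]$success <-
        patient_response(p_s, assistance, difficulty) >= 0.5
    imu <- if ("imu" %in% modalities) gen_imu_stream(p_s, trials, fs = fs_imu)
    emg <- if ("emg" %in% modalities) gen_emg_stream(p_s, trials, fs = fs_emg)
    sessions[[s]] <- list(session = s, capability = cap, trials = trials,
                          imu = imu, emg = emg)
    cap <- min(max(cap + patient$learn_rate, 0), 1)
  }
  structure(list(sessions = sessions, anchors = patient$anchors,
                 config = config),
            class = "course_record")
}

#' @export
print.course_record <- function(x, ...) {
  cat(sprintf("<course_record> %d sessions x %d trials, anchors FMA %g -> %g\n",
              length(x$sessions), length(x$sessions[[1]]$trials),
              x$anchors$fma_0, x$anchors$fma_T))
  invisible(x)
}

#' Write generator outputs to disk
#'
#' Writers for the interchange formats: sEMG CSV (`time_s, ch_00..`), IMU
#' CSV (`time_s, gyro_*, accel_*`), trial logs as JSON Lines, and a course
#' manifest JSON.
#'
#' @param x a `signal_stream` (for the CSV writers), list of `trial_spec`
#'   (JSONL writer), or `course_record` (manifest writer).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stream_csv <- function(x, path) {
  stopifnot(inherits(x, "signal_stream"))
  df <- data.frame(time_s = stream_time(x), t(x$samples))
  names(df) <- c("time_s", x$channel_names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
write_trials_jsonl <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in x) {
    rec <- list(trial_id = tr$trial_id, t_start_s = tr$t_start,
                t_end_s = tr$t_end, D_cm = tr$distance_D, W_cm = tr$width_W,
                success = tr$success, completion_time_s = tr$duration_T)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a trial log written by [write_trials_jsonl()]
#' @param path JSONL file path.
#' @return list of `trial_spec`.
#' @export
read_trials_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tr <- trial_spec(rec$trial_id, rec$t_start_s, rec$t_end_s,
                     rec$D_cm, rec$W_cm,
                     success = if (is.null(rec$success)) NA else rec$success)
    tr
  })
}
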