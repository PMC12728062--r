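#' Simulate one closed-loop training session
#'
#' Runs the perception-assessment-assistance cycle: each 200 ms control
#' cycle produces an instantaneous score S_t, its exponential smoothing
#' S~_t, and one AAN controller update of assistance u_t and difficulty
#' d_t; the virtual patient's performance responds to the current (u, d).
#'
#' Two score sources are supported. `"oracle"` draws S_t directly from the
#' virtual patient's response model ([patient_response()]) — appropriate
#' for studying the controller/patient dynamics in isolation. `"pipeline"`
#' generates raw sEMG/IMU signals per trial, preprocesses them, extracts
#' per-window features and scores them with a fitted [fit_scoring_model()]
#' bundle mapped through [composite_score()].
#'
#' @param patient a [virtual_patient()].
#' @param cfg a [control_config()].
#' @param n_cycles number of control cycles (default 300, i.e. one minute
#'   at 200 ms).
#' @param u0,d0 initial assistance and difficulty.
#' @param score_source `"oracle"` or `"pipeline"`.
#' @param bundle fitted `model_bundle` (required for `"pipeline"`).
#' @param scoring_cfg a [scoring_config()] (smoothing rate etc.).
#' @param cycles_per_trial control cycles per simulated trial (oracle
#'   mode), default 20 (15 trials in a 300-cycle session).
#' @param sigma_t constant score uncertainty fed to the controller
#'   (oracle mode), default 0.
#' @return object of class `session_record`: list with `trace` (data frame
#'   `cycle, t_s, S_t, S_smooth, sigma_t, u_t, d_t, mode`), `trials`
#'   (data frame `trial_id, success`), `summary` (named vector `mean_u,
#'   mean_d, mean_S_smooth, success_rate, tracking_error`), and the final
#'   `state`.
#' @export
run_session <- function(patient, cfg = control_config(), n_cycles = 300,
                        u0 = 0.62, d0 = NULL,
                        score_source = c("oracle", "pipeline"),
                        bundle = NULL, scoring_cfg = scoring_config(),
                        cycles_per_trial = 20, sigma_t = 0) {
  score_source <- match.arg(score_source)
  if (is.null(d0)) d0 <- patient$capability
  state <- control_state(u = u0, d = d0)
  lam <- scoring_cfg$lambda_smooth

  if (score_source == "pipeline") {
    if (is.null(bundle)) stop("pipeline scoring needs a fitted model bundle")
    return(run_session_pipeline(patient, cfg, bundle, scoring_cfg,
                                n_cycles, u0, d0))
  }

  trace <- matrix(NA_real_, n_cycles, 6)
  modes <- character(n_cycles)
  trial_succ <- logical(0)
  S_sm <- NULL
  for (k in seq_len(n_cycles)) {
    S <- patient_response(patient, state$u, state$d)
    S_sm <- if (is.null(S_sm)) S else lam * S + (1 - lam) * S_sm
    state <- aan_step(state, S_sm, sigma_t = sigma_t,
                      emg_level = 1, speed = 10, cfg = cfg)
    trace[k, ] <- c(k, (k - 1) * cfg$cycle_s, S, S_sm, sigma_t, NA)
    trace[k, 6] <- state$u
    modes[k] <- state$mode
    if (k %% cycles_per_trial == 0)
      trial_succ <- c(trial_succ,
                      patient_response(patient, state$u, state$d) >= 0.5)
    if (k == 1) d_col <- numeric(n_cycles)
    d_col[k] <- state$d
  }
  trace_df <- data.frame(cycle = trace[, 1], t_s = trace[, 2],
                         S_t = trace[, 3], S_smooth = trace[, 4],
                         sigma_t = trace[, 5], u_t = trace[, 6],
                         d_t = d_col, mode = modes)
  summarize_session(trace_df, trial_succ, state, cfg)
}

summarize_session <- function(trace_df, trial_succ, state, cfg) {
  summary <- c(mean_u = mean(trace_df$u_t),
               mean_d = mean(trace_df$d_t),
               mean_S_smooth = mean(trace_df$S_smooth),
               success_rate = if (length(trial_succ)) mean(trial_succ) else NA,
               tracking_error = mean(abs(trace_df$S_smooth - cfg$S_star)))
  structure(list(trace = trace_df,
                 trials = data.frame(trial_id = seq_along(trial_succ),
                                     success = trial_succ),
                 summary = summary, state = state),
            class = "session_record")
}

# Full-pipeline session: per trial, synthesize signals, preprocess,
# window, featurize, score with the bundle, then run one controller update
# per window cycle.
run_session_pipeline <- function(patient, cfg, bundle, scoring_cfg,
                                 n_cycles, u0, d0) {
  state <- control_state(u = u0, d = d0)
  lam <- scoring_cfg$lambda_smooth
  # composite coefficients must span the bundle's task set
  M <- length(bundle$base)
  if (length(scoring_cfg$alpha_m) != M) {
    scoring_cfg$alpha_m <- rep(1 / M, M)
    scoring_cfg$tasks <- bundle$config$tasks
  }
  S_sm <- NULL
  rows <- list()
  trial_succ <- logical(0)
  cyc <- 0L
  trial_id <- 0L
  while (cyc < n_cycles) {
    trial_id <- trial_id + 1L
    # patient's effective capability responds to assistance and difficulty
    p_eff <- patient
    p_eff$capability <- min(max(
      patient$capability + 0.25 * state$u - 0.15 * state$d, 0.05), 1)
    trials <- make_trials(1, difficulty = state$d, duration_s = 5, gap_s = 0.5)
    trials[[1]]$success <- patient_response(p_eff, state$u, state$d) >= 0.5
    trial_succ <- c(trial_succ, trials[[1]]$success)
    imu <- gen_imu_stream(p_eff, trials)
    emg <- gen_emg_stream(p_eff, trials)
    cond <- emg_condition(emg)
    angle <- integrate_gyro(imu, channels = "gyro_y")
    segs <- segment_and_window(angle, trials,
                               window_ms = scoring_cfg_window_ms(), overlap = 0.5)
    X <- session_window_features(angle, cond$envelope, segs[[1]],
                                 patient$rom_base)
    if (nrow(X) == 0) next
    zhat <- predict_scores(bundle, X[, bundle$feature_names, drop = FALSE])
    S_win <- composite_score(zhat, scoring_cfg)
    sig <- score_uncertainty(bundle, X[, bundle$feature_names, drop = FALSE])
    for (j in seq_along(S_win)) {
      cyc <- cyc + 1L
      if (cyc > n_cycles) break
      S_sm <- if (is.null(S_sm)) S_win[j] else lam * S_win[j] + (1 - lam) * S_sm
      emg_lvl <- mean(cond$envelope$samples)
      state <- aan_step(state, S_sm, sigma_t = sig[j], emg_level = emg_lvl,
                        speed = 10, emg_baseline = emg_lvl, cfg = cfg)
      rows[[cyc]] <- data.frame(cycle = cyc, t_s = (cyc - 1) * cfg$cycle_s,
                                S_t = S_win[j], S_smooth = S_sm,
                                sigma_t = sig[j], u_t = state$u,
                                d_t = state$d, mode = state$mode)
    }
  }
  trace_df <- do.call(rbind, rows)
  summarize_session(trace_df, trial_succ, state, cfg)
}

scoring_cfg_window_ms <- function() 200

#' Per-window feature matrix for one task segment
#'
#' Kinematic features of the windowed angle plus envelope summary features
#' — the compact online feature set used by the closed-loop simulator.
#'
#' @param angle single-channel angle `signal_stream` (deg).
#' @param envelope EMG envelope `signal_stream` (any channel count; the
#'   first two are used for the co-contraction index).
#' @param segment one element of [segment_and_window()].
#' @param rom_base patient baseline ROM, degrees.
#' @return data frame, one row per window.
#' @export
session_window_features <- function(angle, envelope, segment, rom_base) {
  wins <- segment$windows
  if (nrow(wins) == 0)
    return(data.frame())
  ratio <- envelope$fs / angle$fs
  out <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    a <- angle$samples[1, wins$start_idx[i]:(wins$end_idx[i] - 1)]
    e_lo <- max(1L, round((wins$start_idx[i] - 1) * ratio) + 1L)
    e_hi <- min(ncol(envelope$samples), round((wins$end_idx[i] - 1) * ratio))
    e <- envelope$samples[, e_lo:e_hi, drop = FALSE]
    kf <- kinematic_features(a, angle$fs, rom_base)
    cc <- if (nrow(e) >= 2) cci(e[1, ], e[2, ]) else NA_real_
    out[[i]] <- c(kf, env_mean = mean(e[1, ]), env_peak = max(e[1, ]),
                  CCI = if (is.na(cc)) 0 else cc)
  }
  df <- as.data.frame(do.call(rbind, out))
  df$t_center_s <- wins$t_center_s
  df
}

#' Simulate a full training course in closed loop
#'
#' Runs [run_session()] repeatedly. Between sessions the patient's
#' capability follows a zone-of-proximal-development rule:
#' `c' = clip(c + learn_rate * exp(-(d_bar - c)^2 / (2 * zpd_width^2)) *
#' (1 - 0.5 * u_bar), 0, 1)` — learning is fastest when the session's mean
#' difficulty matches capability and is damped by heavy assistance. Each
#' session starts from the previous session's final assistance and
#' difficulty.
#'
#' @inheritParams run_session
#' @param n_sessions number of sessions.
#' @param zpd_width width of the learning kernel, default 0.35.
#' @return object of class `course_sim`: list with `sessions` (list of
#'   `session_record`), `capability` (per-session vector), and `summary`
#'   (data frame of per-session means).
#' @export
run_course_sim <- function(patient, cfg = control_config(), n_sessions = 20,
                           n_cycles = 300, u0 = 0.62, d0 = 0.35,
                           scoring_cfg = scoring_config(),
                           zpd_width = 0.35, ...) {
  cap <- patient$capability
  sessions <- vector("list", n_sessions)
  caps <- numeric(n_sessions)
  u_cur <- u0; d_cur <- d0
  for (s in seq_len(n_sessions)) {
    p_s <- patient
    p_s$capability <- cap
    rec <- run_session(p_s, cfg, n_cycles = n_cycles, u0 = u_cur, d0 = d_cur,
                       scoring_cfg = scoring_cfg, ...)
    sessions[[s]] <- rec
    caps[s] <- cap
    u_bar <- rec$summary["mean_u"]
    d_bar <- rec$summary["mean_d"]
    gain <- exp(-(d_bar - cap)^2 / (2 * zpd_width^2)) * (1 - 0.5 * u_bar)
    cap <- min(max(cap + patient$learn_rate * gain, 0), 1)
    u_cur <- rec$state$u
    d_cur <- rec$state$d
  }
  summary <- data.frame(
    session = seq_len(n_sessions),
    capability = caps,
    t(vapply(sessions, function(r) r$summary, numeric(5))))
  structure(list(sessions = sessions, capability = caps, summary = summary),
            class = "course_sim")
}

#' @export
print.course_sim <- function(x, ...) {
  cat(sprintf(
    "<course_sim> %d sessions: mean u %0.2f -> %0.2f, d %0.2f -> %0.2f, success %0.2f -> %0.2f\n",
    nrow(x$summary),
    x$summary$mean_u[1], x$summary$mean_u[nrow(x$summary)],
    x$summary$mean_d[1], x$summary$mean_d[nrow(x$summary)],
    x$summary$success_rate[1], x$summary$success_rate[nrow(x$summary)]))
  invisible(x)
}
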