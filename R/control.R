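#' AAN controller configuration
#'
#' Constants of the dual-channel assistance-as-needed law: assistance gain
#' `k_u = 0.05`, difficulty gain magnitude `k_d = 0.08`, target score
#' `S* = 0.75` (target band 0.7-0.8), rate limit 0.02 per 200 ms cycle,
#' dead zone 0.05, hysteresis band [0.65, 0.85], protection threshold 0.4,
#' uncertainty threshold 0.15, and the disengagement rule (sEMG below 10%
#' of baseline and speed below 2 deg/s sustained for more than 5 s).
#'
#' @param k_u assistance gain (> 0).
#' @param k_d difficulty gain magnitude (> 0).
#' @param k_d_sign +1 (default) makes difficulty rise with performance
#'   above target; -1 reproduces the literal inverse-gain form.
#' @param S_star target score in `[0.7, 0.8]` typically.
#' @param r_max per-cycle rate limit on both channels.
#' @param dead_zone no-update zone around the target (0 < eps <
#'   theta_high - theta_low).
#' @param theta_low,theta_high hysteresis band thresholds.
#' @param u_min,u_max,d_min,d_max channel bounds.
#' @param theta_safe protection-mode score floor.
#' @param sigma_thresh uncertainty threshold for gain degradation.
#' @param cycle_s control cycle, seconds.
#' @param disengage_emg_frac,disengage_speed,disengage_sustain_s
#'   withdrawal-detection thresholds (fraction of EMG baseline, deg/s,
#'   seconds).
#' @return object of class `control_config`.
#' @export
control_config <- function(k_u = 0.05, k_d = 0.08, k_d_sign = 1,
                           S_star = 0.75, r_max = 0.02, dead_zone = 0.05,
                           theta_low = 0.65, theta_high = 0.85,
                           u_min = 0, u_max = 1, d_min = 0, d_max = 1,
                           theta_safe = 0.4, sigma_thresh = 0.15,
                           cycle_s = 0.2,
                           disengage_emg_frac = 0.1, disengage_speed = 2,
                           disengage_sustain_s = 5) {
  stopifnot(k_u > 0, k_d > 0, abs(k_d_sign) == 1, r_max > 0,
            u_min < u_max, d_min < d_max,
            dead_zone > 0, dead_zone < theta_high - theta_low,
            theta_low < theta_high, cycle_s > 0)
  structure(as.list(environment()), class = "control_config")
}

#' AAN controller state
#'
#' @param u assistance level in `[u_min, u_max]`.
#' @param d difficulty level in `[d_min, d_max]`.
#' @param mode one of `"normal"`, `"protect"`, `"degraded_gain"`,
#'   `"paused"`.
#' @param dir_u,dir_d hysteresis direction latches (-1 / 0 / +1).
#' @param low_time accumulated low-activity time, seconds.
#' @return object of class `control_state`.
#' @export
control_state <- function(u = 0.5, d = 0.3, mode = "normal",
                          dir_u = 0, dir_d = 0, low_time = 0) {
  structure(list(u = u, d = d, mode = mode, dir_u = dir_u, dir_d = dir_d,
                 low_time = low_time, recalibrate = FALSE, alert = FALSE),
            class = "control_state")
}

# shared channel update: dead zone -> gain scaling -> rate limit -> bounds,
# with a direction latch gated by the hysteresis band
channel_step <- function(value, err, gain, dir_prev, S_tilde, cfg,
                         lo, hi, switch_up_below = TRUE) {
  if (abs(err) < cfg$dead_zone)
    return(list(value = value, dir = dir_prev))
  step <- gain * err
  step <- sign(step) * min(abs(step), cfg$r_max)
  new_dir <- sign(step)
  if (dir_prev != 0 && new_dir != dir_prev) {
    # direction reversal must be armed by a band crossing
    allowed <- if ((new_dir > 0) == switch_up_below)
      S_tilde < cfg$theta_low else S_tilde > cfg$theta_high
    if (!allowed) return(list(value = value, dir = dir_prev))
  }
  v <- min(max(value + step, lo), hi)
  list(value = v, dir = if (v != value) new_dir else dir_prev)
}

#' Assistance channel update
#'
#' `u_t = clip(u_{t-1} + k_u (S* - S~_t), u_min, u_max)` subject to the
#' dead zone, rate limit and hysteresis latch; when the score uncertainty
#' exceeds `sigma_thresh` the effective gain is halved first.
#'
#' @param state a [control_state()].
#' @param S_tilde smoothed score in `[0, 1]`.
#' @param sigma_t score uncertainty (>= 0).
#' @param cfg a [control_config()].
#' @return updated `control_state`.
#' @export
update_assist <- function(state, S_tilde, sigma_t = 0,
                          cfg = control_config()) {
  stopifnot(inherits(state, "control_state"), S_tilde >= 0, S_tilde <= 1)
  gain <- if (sigma_t > cfg$sigma_thresh) cfg$k_u / 2 else cfg$k_u
  res <- channel_step(state$u, cfg$S_star - S_tilde, gain, state$dir_u,
                      S_tilde, cfg, cfg$u_min, cfg$u_max,
                      switch_up_below = TRUE)
  state$u <- res$value
  state$dir_u <- res$dir
  state
}

#' Difficulty channel update
#'
#' Difficulty rises when the smoothed score exceeds the target:
#' `d_t = clip(d_{t-1} + k_d_sign * |k_d| (S~_t - S*), d_min, d_max)`,
#' with the same dead zone, rate limit and hysteresis as the assistance
#' channel.
#'
#' @inheritParams update_assist
#' @return updated `control_state`.
#' @export
update_difficulty <- function(state, S_tilde, cfg = control_config()) {
  stopifnot(inherits(state, "control_state"), S_tilde >= 0, S_tilde <= 1)
  res <- channel_step(state$d, cfg$k_d_sign * (S_tilde - cfg$S_star),
                      cfg$k_d, state$dir_d, S_tilde, cfg,
                      cfg$d_min, cfg$d_max, switch_up_below = FALSE)
  state$d <- res$value
  state$dir_d <- res$dir
  state
}

#' Safety overrides
#'
#' Determines the controller mode for the current cycle:
#' \itemize{
#'   \item score lower-bound protection: `S~_t < theta_safe` forces
#'     `protect` (assistance ramps to `u_max` at the rate limit, difficulty
#'     frozen against increase, alert flag set);
#'   \item physiological monitoring: sEMG below `disengage_emg_frac` of
#'     baseline and speed below `disengage_speed` sustained longer than
#'     `disengage_sustain_s` forces `paused`;
#'   \item uncertainty protection: `sigma_t > sigma_thresh` sets
#'     `degraded_gain` (halved assist gain) and the recalibration flag.
#' }
#' Precedence: protect > paused > degraded_gain > normal.
#'
#' @inheritParams update_assist
#' @param emg_level current sEMG activation level.
#' @param emg_baseline calibrated sEMG baseline level.
#' @param speed current joint speed, deg/s.
#' @return updated `control_state` with `mode` set.
#' @export
apply_safety <- function(state, S_tilde, sigma_t, emg_level, speed,
                         emg_baseline = 1, cfg = control_config()) {
  stopifnot(inherits(state, "control_state"))
  low <- emg_level < cfg$disengage_emg_frac * emg_baseline &&
    speed < cfg$disengage_speed
  state$low_time <- if (low) state$low_time + cfg$cycle_s else 0
  state$recalibrate <- FALSE
  state$alert <- FALSE
  if (S_tilde < cfg$theta_safe) {
    state$mode <- "protect"
    state$alert <- TRUE
  } else if (state$low_time > cfg$disengage_sustain_s) {
    state$mode <- "paused"
  } else if (sigma_t > cfg$sigma_thresh) {
    state$mode <- "degraded_gain"
    state$recalibrate <- TRUE
  } else {
    state$mode <- "normal"
  }
  state
}

#' One full AAN control cycle
#'
#' Applies the safety overrides, then the channel updates appropriate to
#' the resulting mode: `protect` ramps assistance toward `u_max` at the
#' rate limit with difficulty frozen; `paused` freezes both channels;
#' otherwise both channels update normally (with degraded gain when the
#' uncertainty override is active).
#'
#' @inheritParams apply_safety
#' @return updated `control_state`.
#' @export
aan_step <- function(state, S_tilde, sigma_t = 0, emg_level = 1, speed = 10,
                     emg_baseline = 1, cfg = control_config()) {
  state <- apply_safety(state, S_tilde, sigma_t, emg_level, speed,
                        emg_baseline, cfg)
  if (state$mode == "protect") {
    state$u <- min(state$u + cfg$r_max, cfg$u_max)
    state$dir_u <- 1
  } else if (state$mode != "paused") {
    state <- update_assist(state, S_tilde, sigma_t, cfg)
    state <- update_difficulty(state, S_tilde, cfg)
  }
  state
}

#' Map scalar difficulty to VR task parameters
#'
#' Linear mapping of `d` in [0, 1] onto target diameter 15 -> 5 cm,
#' movement speed 0.1 -> 0.5 m/s and reach distance 20 -> 50 cm; the Fitts
#' index of difficulty of the mapped geometry rises with `d`.
#'
#' @param d difficulty in `[0, 1]`.
#' @return named vector `diameter_cm, speed_mps, distance_cm, fitts_ID`.
#' @export
difficulty_params <- function(d) {
  stopifnot(all(d >= 0), all(d <= 1))
  W <- 15 - 10 * d
  D <- 20 + 30 * d
  c(diameter_cm = W, speed_mps = 0.1 + 0.4 * d, distance_cm = D,
    fitts_ID = log2(D / W + 1))
}
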