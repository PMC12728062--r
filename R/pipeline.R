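#' Segment-level feature table for a generated course
#'
#' Runs the standard preprocessing chain on every session of a
#' [gen_course()] record (EMG conditioning, gyro integration, trial
#' segmentation) and extracts the per-segment feature bank: kinematic
#' features of the joint angle, time- and frequency-domain features of the
#' first EMG channel, the agonist/antagonist co-contraction index and the
#' Fitts index of difficulty.
#'
#' @param course a `course_record` from [gen_course()].
#' @return data frame with one row per trial segment: `session`,
#'   `trial_id`, `capability`, the feature columns, and segment quality
#'   `Q`.
#' @export
course_features <- function(course) {
  stopifnot(inherits(course, "course_record"))
  rows <- list()
  for (sess in course$sessions) {
    cond <- emg_condition(sess$emg)
    angle <- integrate_gyro(sess$imu, channels = "gyro_y")
    segs <- segment_and_window(angle, sess$trials)
    tf <- task_features(sess$trials)
    fs_ratio <- sess$emg$fs / angle$fs
    for (i in seq_along(segs)) {
      seg <- segs[[i]]
      a <- angle$samples[1, seg$start_idx:(seg$end_idx - 1)]
      e_lo <- max(1L, round((seg$start_idx - 1) * fs_ratio) + 1L)
      e_hi <- min(ncol(cond$filtered$samples),
                  round((seg$end_idx - 1) * fs_ratio))
      emg1 <- cond$filtered$samples[1, e_lo:e_hi]
      env <- cond$envelope$samples[, e_lo:e_hi, drop = FALSE]
      kf <- kinematic_features(a, angle$fs, rom_base = 60)
      tfeat <- emg_time_features(emg1)
      ffeat <- emg_freq_features(emg1, sess$emg$fs)
      cc <- cci(env[1, ], env[2, ])
      rows[[length(rows) + 1]] <- data.frame(
        session = sess$session, trial_id = seg$trial_id,
        capability = sess$capability,
        t(kf), t(tfeat), t(ffeat),
        CCI = if (is.na(cc)) 0 else cc,
        fitts_ID = tf$per_trial$ID[i], Q = seg$Q)
    }
  }
  do.call(rbind, rows)
}

#' Proxy labels for a course feature table
#'
#' Builds the blended window/segment proxy-label series for a course:
#' session scores are linearly interpolated between the clinical anchors,
#' refined biomechanically for rows assigned to the `anchored` source, and
#' replaced by simulated expert ratings (rescaled back to the clinical
#' scale) for the `expert` source. Source assignment follows the 80/15/5
#' data-share blend.
#'
#' @param feat data frame from [course_features()].
#' @param anchors clinical anchors list (`fma_0`, `fma_T`).
#' @param n_sessions total sessions in the course.
#' @param weights source shares, default `c(0.80, 0.15, 0.05)`.
#' @param kappa biomechanical anchoring gain, default 0.05.
#' @return data frame `session, trial_id, proxy_fma, source`.
#' @export
course_proxy_labels <- function(feat, anchors, n_sessions,
                                weights = c(0.80, 0.15, 0.05),
                                kappa = 0.05) {
  fma_s <- interpolate_proxy(anchors$fma_0, anchors$fma_T, n_sessions,
                             feat$session)
  src <- blend_labels(nrow(feat), weights)
  z <- stats::ave(feat$ROMn, feat$session,
                  FUN = function(v) if (stats::sd(v) > 0)
                    (v - mean(v)) / stats::sd(v) else v * 0)
  proxy <- fma_s
  proxy[src == "anchored"] <- anchor_proxy(fma_s[src == "anchored"],
                                           z[src == "anchored"], kappa)
  if (any(src == "expert")) {
    idx <- src == "expert"
    r <- make_expert_ratings(fma_s[idx], lo = 0, hi = 66)
    proxy[idx] <- r / 10 * 66
  }
  data.frame(session = feat$session, trial_id = feat$trial_id,
             proxy_fma = proxy, source = src)
}

#' Generate a multi-subject labelled cohort
#'
#' Convenience wrapper used by the cross-validation experiments: draws a
#' cohort of improving virtual patients with heterogeneous baseline
#' capability, generates their courses, extracts segment features and
#' blended proxy labels.
#'
#' @param n_subjects cohort size.
#' @param n_sessions,trials_per_session course scale.
#' @param seed integer seed.
#' @return list with `X` (feature matrix), `y` (proxy FMA labels),
#'   `groups` (subject ids), `feat` (full feature table).
#' @export
make_cohort <- function(n_subjects = 12, n_sessions = 6,
                        trials_per_session = 4, seed = 1L) {
  set.seed(seed)
  Xs <- list()
  for (s in seq_len(n_subjects)) {
    cap0 <- stats::runif(1, 0.2, 0.55)
    fma0 <- round(15 + 40 * cap0)
    lr <- stats::runif(1, 0.03, 0.06)
    fmaT <- min(66, round(fma0 + 66 * lr * (n_sessions - 1) * 0.8))
    p <- virtual_patient(capability = cap0, noise_sd = 0.05,
                         learn_rate = lr, tremor_amp = 1.5 * (1 - cap0),
                         cocontraction = 0.5 * (1 - cap0),
                         anchors = list(fma_0 = fma0, fma_T = fmaT,
                                        arat_0 = 20, arat_T = 28))
    course <- gen_course(
      p, course_config(n_sessions = n_sessions,
                       trials_per_session = trials_per_session,
                       trial_duration_s = 4, gap_s = 1,
                       seed = sample.int(1e6, 1)))
    feat <- course_features(course)
    lab <- course_proxy_labels(feat, p$anchors, n_sessions)
    feat$proxy_fma <- lab$proxy_fma
    feat$subject <- s
    Xs[[s]] <- feat
  }
  all <- do.call(rbind, Xs)
  drop_cols <- c("session", "trial_id", "capability", "proxy_fma",
                 "subject", "Q")
  X <- as.matrix(all[, setdiff(names(all), drop_cols)])
  X[!is.finite(X)] <- 0
  list(X = X, y = all$proxy_fma, groups = all$subject, feat = all)
}
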