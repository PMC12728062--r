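#' Hampel/MAD artifact cleaning
#'
#' Samples deviating from the windowed median by more than `n_mad` robust
#' standard deviations (1.4826 x MAD) are replaced by the window median.
#' Missing samples (NA) are linearly interpolated when they make up at most
#' 10% of the channel; otherwise the channel is flagged low-quality (its Q
#' drops below the usual acceptance threshold) but is still interpolated
#' rather than dropped. The returned mask marks every replaced or
#' interpolated sample, and `Q` is the fraction of untouched samples.
#'
#' @param x a `signal_stream`.
#' @param half_window half window length in samples (>= 1), default 5.
#' @param n_mad outlier threshold in robust SDs, default 3.
#' @return list with `stream` (cleaned), `mask` (logical channels x time,
#'   TRUE where a sample was replaced), and `Q` (scalar quality in [0, 1]).
#' @export
hampel_clean <- function(x, half_window = 5, n_mad = 3) {
  stopifnot(inherits(x, "signal_stream"), half_window >= 1)
  s <- x$samples
  mask <- matrix(FALSE, nrow(s), ncol(s))
  n <- ncol(s)
  for (ch in seq_len(nrow(s))) {
    v <- s[ch, ]
    na <- is.na(v)
    if (any(na)) {
      idx <- which(!na)
      if (length(idx) < 2) stop("channel almost entirely missing")
      v <- stats::approx(idx, v[idx], xout = seq_len(n), rule = 2)$y
      mask[ch, na] <- TRUE
    }
    h <- pracma::hampel(v, k = half_window, t0 = n_mad)
    s[ch, ] <- h$y
    mask[ch, h$ind] <- TRUE
  }
  out <- x
  out$samples <- s
  list(stream = out, mask = mask, Q = 1 - mean(mask))
}

#' Teager-Kaiser energy operator
#'
#' `psi[x](n) = x(n)^2 - x(n-1) x(n+1)`; endpoints are copied from their
#' neighbours. For a pure sinusoid `A sin(w n)` the operator is the
#' constant `A^2 sin(w)^2`.
#'
#' @param x numeric vector (length >= 3).
#' @return numeric vector of the same length.
#' @export
tkeo <- function(x) {
  n <- length(x)
  if (n < 3) stop("signal must have at least 3 samples")
  psi <- numeric(n)
  psi[2:(n - 1)] <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  psi[1] <- psi[2]
  psi[n] <- psi[n - 1]
  psi
}

#' TKEO burst/onset detection with adaptive threshold
#'
#' Computes the Teager-Kaiser energy of a single-channel stream and declares
#' an onset when the energy exceeds `baseline_mean + threshold_k *
#' baseline_sd` for at least `min_consecutive` samples. The baseline is the
#' first `baseline_s` seconds of the stream. After a detection, the energy
#' must fall back below threshold before a new onset can be declared.
#'
#' @param x single-channel `signal_stream`.
#' @param threshold_k threshold in baseline SDs, default 8.
#' @param min_consecutive minimum consecutive supra-threshold samples,
#'   default 10.
#' @param baseline_s baseline duration, seconds, default 0.5.
#' @param smooth_n optional moving-average length (samples) applied to the
#'   energy before thresholding, default 5.
#' @return numeric vector of onset times in seconds (stream clock).
#' @export
tkeo_onset <- function(x, threshold_k = 8, min_consecutive = 10,
                       baseline_s = 0.5, smooth_n = 5) {
  stopifnot(inherits(x, "signal_stream"), nrow(x$samples) == 1)
  v <- as.numeric(x$samples[1, ])
  psi <- tkeo(v)
  if (smooth_n > 1)
    psi <- stats::filter(psi, rep(1 / smooth_n, smooth_n), sides = 2) |>
      as.numeric()
  nb <- max(3, round(baseline_s * x$fs))
  base <- psi[seq_len(min(nb, length(psi)))]
  base <- base[!is.na(base)]
  thr <- mean(base) + threshold_k * stats::sd(base)
  if (!is.finite(thr)) return(numeric(0))
  above <- !is.na(psi) & psi > thr
  onsets <- numeric(0)
  run <- 0L
  armed <- TRUE
  for (i in seq_along(above)) {
    if (above[i]) {
      run <- run + 1L
      if (armed && run >= min_consecutive) {
        onsets <- c(onsets, x$t0 + (i - run) / x$fs)
        armed <- FALSE
      }
    } else {
      run <- 0L
      armed <- TRUE
    }
  }
  onsets
}

#' Segment a stream by trial log and tile with sliding windows
#'
#' One task segment per trial (delimited by the VR trial log); each segment
#' is tiled with sliding windows of `window_ms` at the given overlap.
#' Windows use half-open sample intervals and never cross segment
#' boundaries. A segment shorter than one window yields zero windows with a
#' warning.
#'
#' @param x a `signal_stream`.
#' @param trials list of [trial_spec()] whose times fall inside the stream.
#' @param window_ms window length, ms (default 200).
#' @param overlap fractional overlap in `[0, 1)`, default 0.5.
#' @param mask optional logical matrix from [hampel_clean()] used to compute
#'   per-segment quality `Q` (fraction of valid samples).
#' @return list of task segments; each has `trial_id`, `start_idx`,
#'   `end_idx` (half-open, 1-based), `t_start`, `t_end`, `Q`, and `windows`
#'   (data frame with `start_idx`, `end_idx`, `t_center_s`).
#' @export
segment_and_window <- function(x, trials, window_ms = 200, overlap = 0.5,
                               mask = NULL) {
  stopifnot(inherits(x, "signal_stream"), overlap >= 0, overlap < 1)
  w <- max(1L, round(window_ms / 1000 * x$fs))
  step <- max(1L, round(w * (1 - overlap)))
  tt <- stream_time(x)
  out <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    idx <- which(tt >= tr$t_start & tt < tr$t_end)
    if (length(idx) == 0) stop("trial ", tr$trial_id, " outside stream range")
    n_seg <- length(idx)
    if (n_seg < w) {
      warning("segment ", tr$trial_id, " shorter than one window")
      wins <- data.frame(start_idx = integer(0), end_idx = integer(0),
                         t_center_s = numeric(0))
    } else {
      starts <- seq(1L, n_seg - w + 1L, by = step)
      wins <- data.frame(
        start_idx = idx[1] + starts - 1L,
        end_idx = idx[1] + starts + w - 1L,   # half-open
        t_center_s = tt[idx[1] + starts - 1L] + (w / 2) / x$fs
      )
    }
    Q <- if (is.null(mask)) 1 else 1 - mean(mask[, idx])
    out[[i]] <- list(trial_id = tr$trial_id, start_idx = idx[1],
                     end_idx = idx[n_seg] + 1L, t_start = tt[idx[1]],
                     t_end = tt[idx[n_seg]] + 1 / x$fs, Q = Q,
                     windows = wins)
  }
  out
}
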