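#' Cross-correlation lag estimation
#'
#' Estimates the propagation lag between two signals (e.g. the EMG envelope
#' and joint angular velocity) as the lag maximizing the normalized
#' cross-correlation over `[-max_lag, max_lag]`. Ties are broken toward the
#' smallest absolute lag. Positive lag means `y` trails `x` by `dt`.
#'
#' @param x,y single-channel `signal_stream`s at the same sampling rate (or
#'   numeric vectors with `fs` supplied).
#' @param max_lag maximum lag to search, seconds.
#' @param fs sampling rate when `x`, `y` are plain vectors.
#' @return estimated lag in seconds.
#' @export
estimate_lag <- function(x, y, max_lag = 0.5, fs = NULL) {
  if (inherits(x, "signal_stream")) { fs <- x$fs; x <- as.numeric(x$samples[1, ]) }
  if (inherits(y, "signal_stream")) { y <- as.numeric(y$samples[1, ]) }
  stopifnot(!is.null(fs), length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cross-correlation undefined for constant signals")
  L <- min(floor(max_lag * fs), length(x) - 1)
  xc <- stats::ccf(y, x, lag.max = L, plot = FALSE, demean = TRUE)
  r <- as.numeric(xc$acf)
  lags <- as.numeric(xc$lag)
  best <- which(r == max(r))
  lag <- lags[best[which.min(abs(lags[best]))]]
  lag / fs
}

#' Resample streams onto a shared timeline
#'
#' Resamples each stream onto a common uniform timeline at `target_fs`
#' (default 100 Hz) spanning the overlap of all inputs. Continuous channels
#' use linear interpolation; event/logical channels use zero-order hold.
#' An optional per-stream lag (from [estimate_lag()]) is compensated before
#' interpolation.
#'
#' @param streams named list of `signal_stream`s.
#' @param target_fs target sampling rate, Hz.
#' @param method per-stream interpolation: `"linear"` or `"zoh"`, recycled.
#' @param lags optional numeric vector of lags (s) subtracted per stream.
#' @return named list of resampled `signal_stream`s on the common timeline.
#' @export
resample_align <- function(streams, target_fs = 100, method = "linear",
                           lags = NULL) {
  stopifnot(length(streams) >= 1)
  method <- rep(method, length.out = length(streams))
  if (is.null(lags)) lags <- rep(0, length(streams))
  t_start <- max(vapply(streams, function(s) s$t0, numeric(1)) - lags)
  t_end <- min(vapply(streams, function(s) s$t0 + (ncol(s$samples) - 1) / s$fs,
                      numeric(1)) - lags)
  if (t_end <= t_start) stop("streams have no overlapping time range")
  tt <- seq(t_start, t_end, by = 1 / target_fs)
  out <- vector("list", length(streams))
  names(out) <- names(streams)
  for (i in seq_along(streams)) {
    s <- streams[[i]]
    ts <- stream_time(s) - lags[i]
    interp <- function(v) {
      if (method[i] == "zoh") {
        stats::approx(ts, v, xout = tt, method = "constant", rule = 2)$y
      } else {
        stats::approx(ts, v, xout = tt, method = "linear", rule = 2)$y
      }
    }
    m <- t(apply(s$samples, 1, interp))
    out[[i]] <- signal_stream(m, target_fs, t0 = t_start,
                              modality = s$modality,
                              channel_names = s$channel_names,
                              units = s$units)
  }
  out
}
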