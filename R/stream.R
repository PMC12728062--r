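#' Uniformly sampled multichannel signal stream
#'
#' The common container used throughout the pipeline: a channels x time matrix
#' with a sampling rate, a start time and a modality tag. All preprocessing
#' and feature functions consume and return `signal_stream` objects.
#'
#' @param samples numeric matrix, channels x time (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @param modality one of `"emg"`, `"imu_gyro"`, `"imu_accel"`, `"envelope"`,
#'   `"angle"`, `"torque"`, `"generic"`.
#' @param channel_names optional character vector, one name per channel.
#' @param units free-text unit string (e.g. `"deg/s"`, `"a.u."`).
#'
#' @return an object of class `signal_stream` with fields `samples`, `fs`,
#'   `t0`, `modality`, `channel_names`, `units`.
#' @export
signal_stream <- function(samples, fs, t0 = 0,
                          modality = c("generic", "emg", "imu_gyro",
                                       "imu_accel", "envelope", "angle",
                                       "torque"),
                          channel_names = NULL, units = "") {
  modality <- match.arg(modality)
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- sprintf("ch_%02d", seq_len(nrow(samples)) - 1L)
  if (length(channel_names) != nrow(samples))
    stop("channel_names length must match the number of channels")
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs, t0 = t0, modality = modality,
         channel_names = channel_names, units = units),
    class = "signal_stream"
  )
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("<signal_stream> %s: %d channel(s) x %d samples @ %g Hz, t0=%g s%s\n",
              x$modality, nrow(x$samples), ncol(x$samples), x$fs, x$t0,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Sample times of a stream
#'
#' @param x a `signal_stream`.
#' @return numeric vector of sample times in seconds.
#' @export
stream_time <- function(x) {
  stopifnot(inherits(x, "signal_stream"))
  x$t0 + (seq_len(ncol(x$samples)) - 1L) / x$fs
}

#' Duration of a stream in seconds
#' @param x a `signal_stream`.
#' @return duration (n_samples / fs) in seconds.
#' @export
stream_duration <- function(x) ncol(x$samples) / x$fs

#' Extract a time slice of a stream
#'
#' Half-open interval `[from, to)` in seconds on the stream's own clock.
#'
#' @param x a `signal_stream`.
#' @param from,to slice bounds in seconds.
#' @return a `signal_stream` covering the requested interval.
#' @export
stream_slice <- function(x, from, to) {
  tt <- stream_time(x)
  keep <- tt >= from & tt < to
  if (!any(keep)) stop("empty slice: [", from, ", ", to, ") outside stream")
  out <- x
  out$samples <- x$samples[, keep, drop = FALSE]
  out$t0 <- tt[which(keep)[1L]]
  out
}
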