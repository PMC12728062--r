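#' Filter specification
#'
#' Butterworth designs only; `kind = "notch"` is a 2nd-order IIR notch at
#' `notch_freq` with quality factor `q`.
#'
#' @param kind `"lowpass"`, `"highpass"`, `"bandpass"` or `"notch"`.
#' @param cutoff_hz cutoff frequency (scalar) or band edges (length 2), Hz.
#' @param order filter order (>= 1); ignored for notch.
#' @param notch_freq notch centre frequency, Hz.
#' @param q notch quality factor (centre / bandwidth), default 30.
#' @param mode `"offline"` (zero-phase forward-backward) or `"online"`
#'   (causal single pass).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass", "bandpass", "notch"),
                        cutoff_hz = NULL, order = 2, notch_freq = 50,
                        q = 30, mode = c("offline", "online")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (kind != "notch") {
    stopifnot(!is.null(cutoff_hz), all(cutoff_hz > 0), order >= 1)
    if (kind == "bandpass" && length(cutoff_hz) != 2)
      stop("bandpass needs two cutoff frequencies")
  }
  structure(list(kind = kind, cutoff_hz = cutoff_hz, order = order,
                 notch_freq = notch_freq, q = q, mode = mode),
            class = "filter_spec")
}

# signal::filtfilt / filter applied row-wise to a channels x time matrix
apply_filt <- function(samples, filt, mode) {
  f <- if (mode == "offline") {
    function(x) signal::filtfilt(filt, x)
  } else {
    function(x) as.numeric(signal::filter(filt, x))
  }
  t(apply(samples, 1, f))
}

#' Butterworth (and notch) filtering of a signal stream
#'
#' Offline mode is zero-phase (forward-backward); online mode is causal.
#' DC gain is 1 for lowpass designs. The analog prototype has magnitude
#' `1/sqrt(1 + (w/wc)^(2n))`, i.e. -3.01 dB at the cutoff.
#'
#' @param x a `signal_stream`.
#' @param spec a [filter_spec()].
#' @return filtered `signal_stream`.
#' @export
butterworth_filter <- function(x, spec) {
  stopifnot(inherits(x, "signal_stream"), inherits(spec, "filter_spec"))
  nyq <- x$fs / 2
  if (spec$kind == "notch") {
    if (spec$notch_freq >= nyq) stop("notch frequency at or above Nyquist")
    # 2nd-order IIR notch, bandwidth = f0 / q
    w0 <- spec$notch_freq / nyq
    bw <- w0 / spec$q
    r <- 1 - pi * bw       # pole radius from bandwidth (narrow-band approx)
    th <- pi * w0
    b <- c(1, -2 * cos(th), 1)
    a <- c(1, -2 * r * cos(th), r^2)
    b <- b * sum(a) / sum(b)   # unit DC gain
    filt <- signal::Arma(b = b, a = a)
  } else {
    if (any(spec$cutoff_hz >= nyq)) stop("cutoff at or above Nyquist")
    type <- switch(spec$kind, lowpass = "low", highpass = "high",
                   bandpass = "pass")
    filt <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = type)
  }
  out <- x
  out$samples <- apply_filt(x$samples, filt, spec$mode)
  rownames(out$samples) <- x$channel_names
  out
}

#' Condition a raw sEMG stream
#'
#' 4th-order 20-450 Hz bandpass plus mains notch, then full-wave
#' rectification and low-pass filtering to obtain the non-negative
#' activation envelope e(t).
#'
#' @param x a `signal_stream` with modality `"emg"`, fs >= 900 Hz.
#' @param notch_hz mains frequency to notch out (50 or 60), default 50.
#' @param envelope_lp_hz envelope low-pass cutoff, Hz (default 5; typical
#'   range 3-10).
#' @param mode `"offline"` (zero phase) or `"online"` (causal).
#' @return list with `filtered` (band+notch filtered stream) and `envelope`
#'   (rectified low-passed stream, modality `"envelope"`).
#' @export
emg_condition <- function(x, notch_hz = 50, envelope_lp_hz = 5,
                          mode = c("offline", "online")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "signal_stream"))
  if (x$modality != "emg") stop("emg_condition expects an emg stream")
  if (x$fs < 900) stop("fs must be >= 900 Hz for the 20-450 Hz band")
  band <- butterworth_filter(
    x, filter_spec("bandpass", c(20, min(450, x$fs / 2 * 0.98)), order = 4,
                   mode = mode))
  filtered <- butterworth_filter(
    band, filter_spec("notch", notch_freq = notch_hz, mode = mode))
  rect <- filtered
  rect$samples <- abs(rect$samples)
  env <- butterworth_filter(
    rect, filter_spec("lowpass", envelope_lp_hz, order = 2, mode = mode))
  env$samples[env$samples < 0] <- 0   # clamp filter undershoot
  env$modality <- "envelope"
  list(filtered = filtered, envelope = env)
}

#' Integrate a gyroscope stream to joint angle
#'
#' Cumulative trapezoidal integration per channel; theta(t0) = 0.
#'
#' @param x a `signal_stream` with modality `"imu_gyro"` (deg/s).
#' @param channels channels to integrate (default: all).
#' @return a `signal_stream` of angles in degrees, modality `"angle"`.
#' @export
integrate_gyro <- function(x, channels = NULL) {
  stopifnot(inherits(x, "signal_stream"))
  if (x$modality != "imu_gyro") stop("integrate_gyro expects an imu_gyro stream")
  if (is.null(channels)) channels <- x$channel_names
  s <- x$samples[channels, , drop = FALSE]
  tt <- stream_time(x)
  theta <- t(apply(s, 1, function(w) pracma::cumtrapz(tt, w)[, 1]))
  signal_stream(theta, x$fs, t0 = x$t0, modality = "angle",
                channel_names = channels, units = "deg")
}

#' Position from accelerometer by double integration
#'
#' Acceleration is integrated twice with high-pass drift removal after each
#' integration stage (the raw single integral of acceleration is a
#' velocity, not a position).
#'
#' @param x accelerometer `signal_stream` (m/s^2).
#' @param hp_hz high-pass cutoff used for drift removal, Hz.
#' @return `signal_stream` of positions (m).
#' @export
accel_to_position <- function(x, hp_hz = 0.25) {
  stopifnot(inherits(x, "signal_stream"))
  tt <- stream_time(x)
  hp <- filter_spec("highpass", hp_hz, order = 2)
  int1 <- t(apply(x$samples, 1, function(a) pracma::cumtrapz(tt, a)[, 1]))
  v <- butterworth_filter(signal_stream(int1, x$fs, x$t0), hp)
  int2 <- t(apply(v$samples, 1, function(a) pracma::cumtrapz(tt, a)[, 1]))
  p <- butterworth_filter(signal_stream(int2, x$fs, x$t0), hp)
  p$units <- "m"
  p$channel_names <- x$channel_names
  rownames(p$samples) <- x$channel_names
  p
}
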