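#' Spectral arc length (SPARC) smoothness
#'
#' Arc length of the frequency-normalized magnitude spectrum of a speed
#' profile. The spectrum is zero-padded, normalized by its DC value,
#' truncated at `fc` (default 20 Hz) and further truncated at the adaptive
#' cutoff where the normalized magnitude last exceeds `amp_th` (default
#' 0.05). More negative values indicate less smooth movement.
#'
#' @param speed numeric speed profile (e.g. deg/s), uniformly sampled.
#' @param fs sampling rate, Hz.
#' @param fc maximum cutoff frequency, Hz.
#' @param amp_th adaptive cutoff amplitude threshold.
#' @param padlevel zero-padding exponent (FFT length `2^ceil(log2 n) *
#'   2^padlevel`).
#' @return SPARC value (negative, unitless).
#' @export
sparc <- function(speed, fs, fc = 20, amp_th = 0.05, padlevel = 4) {
  stopifnot(length(speed) >= 4, fs > 0)
  nfft <- 2^(ceiling(log2(length(speed))) + padlevel)
  sp <- c(speed, rep(0, nfft - length(speed)))
  Mf <- Mod(stats::fft(sp))[seq_len(nfft / 2 + 1)]
  f <- (seq_len(nfft / 2 + 1) - 1) * fs / nfft
  if (Mf[1] == 0) return(NA_real_)
  Mf <- Mf / Mf[1]
  keep <- f <= fc
  f <- f[keep]; Mf <- Mf[keep]
  above <- which(Mf >= amp_th)
  sel <- seq(above[1], above[length(above)])
  f <- f[sel]; Mf <- Mf[sel]
  frange <- f[length(f)] - f[1]
  if (frange == 0) return(0)
  -sum(sqrt((diff(f) / frange)^2 + diff(Mf)^2))
}

#' Log dimensionless jerk (LDLJ)
#'
#' `LDLJ = -ln( (T^5 / A^2) * integral of squared jerk )` with `T` the
#' segment duration and `A` the peak speed. Larger (less negative) values
#' indicate smoother movement; the measure is invariant under amplitude
#' scaling of the trajectory.
#'
#' @param angle numeric angle trajectory (deg), uniformly sampled.
#' @param fs sampling rate, Hz.
#' @return LDLJ value (unitless).
#' @export
ldlj <- function(angle, fs) {
  stopifnot(length(angle) >= 5, fs > 0)
  dt <- 1 / fs
  v <- diff(angle) / dt
  jerk <- diff(angle, differences = 3) / dt^3
  A <- max(abs(v))
  if (A == 0) return(NA_real_)
  T <- length(angle) * dt
  dj <- T^5 / A^2 * sum(jerk^2) * dt
  -log(dj)
}

# Fraction of total power in [lo, hi] Hz, raw periodogram
band_power_ratio <- function(x, fs, lo = 4, hi = 12) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]^2
  f <- (seq_along(P) - 1) * fs / n
  tot <- sum(P[-1])
  if (tot == 0) return(0)
  sum(P[f >= lo & f <= hi]) / tot
}

#' Kinematic features of a task segment
#'
#' Range of motion (ROM, max - min), normalized ROM, velocity statistics
#' (mean/peak/SD of speed, time to peak velocity), smoothness (LDLJ,
#' SPARC of the speed profile), the 4-12 Hz tremor power ratio of the
#' velocity, and a 1-D path efficiency (ratio of the minimal excursion to
#' the total variation of the trajectory, capped at 1).
#'
#' @param angle numeric angle trajectory of the segment (deg) or a
#'   single-channel `signal_stream`.
#' @param fs sampling rate, Hz (taken from the stream if given).
#' @param rom_base individual baseline ROM, degrees (> 0).
#' @return named numeric vector: `ROM, ROMn, v_mean, v_peak, v_sd, TTPV,
#'   LDLJ, SPARC, tremor_ratio_4_12, path_efficiency`.
#' @export
kinematic_features <- function(angle, fs = NULL, rom_base) {
  if (inherits(angle, "signal_stream")) {
    fs <- angle$fs
    angle <- as.numeric(angle$samples[1, ])
  }
  stopifnot(!is.null(fs), length(angle) >= 5)
  if (rom_base <= 0) stop("rom_base must be > 0")
  rom <- max(angle) - min(angle)
  v <- diff(angle) * fs
  speed <- abs(v)
  tv <- sum(abs(diff(angle)))
  path_eff <- if (tv == 0) 1 else min(1, 2 * rom / tv)
  c(ROM = rom,
    ROMn = rom / rom_base,
    v_mean = mean(speed),
    v_peak = max(speed),
    v_sd = stats::sd(v),
    TTPV = (which.max(speed) - 1) / fs,
    LDLJ = ldlj(angle, fs),
    SPARC = sparc(speed, fs),
    tremor_ratio_4_12 = band_power_ratio(v, fs),
    path_efficiency = path_eff)
}

#' Assistive energy from torque and angular velocity
#'
#' Trapezoidal integral of torque times angular velocity.
#'
#' @param torque `signal_stream` or numeric vector, N*m.
#' @param omega `signal_stream` or numeric vector, rad/s (aligned with
#'   `torque`).
#' @param fs sampling rate when plain vectors are given.
#' @return assistive work in joules.
#' @export
assist_energy <- function(torque, omega, fs = NULL) {
  if (inherits(torque, "signal_stream")) { fs <- torque$fs; torque <- as.numeric(torque$samples[1, ]) }
  if (inherits(omega, "signal_stream")) omega <- as.numeric(omega$samples[1, ])
  stopifnot(!is.null(fs), length(torque) == length(omega))
  tt <- (seq_along(torque) - 1) / fs
  pracma::trapz(tt, torque * omega)
}
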