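#' Time-domain sEMG features
#'
#' Root mean square, mean absolute value, waveform length, zero crossings,
#' slope sign changes and integrated EMG over one window. ZC and SSC use a
#' noise deadband: a crossing/slope change only counts when the involved
#' amplitude differences exceed `deadband`.
#'
#' @param x numeric vector (one channel, one window).
#' @param deadband amplitude deadband for ZC/SSC, default 0.
#' @return named numeric vector `RMS, MAV, WL, ZC, SSC, IEMG`.
#' @export
emg_time_features <- function(x, deadband = 0) {
  stopifnot(length(x) >= 1)
  n <- length(x)
  d <- diff(x)
  zc <- 0L
  ssc <- 0L
  if (n >= 2) {
    sgn <- x[-n] * x[-1]
    zc <- sum(sgn < 0 & abs(d) > deadband)
  }
  if (n >= 3) {
    d1 <- d[-length(d)]
    d2 <- d[-1]
    ssc <- sum(d1 * d2 < 0 & (abs(d1) > deadband | abs(d2) > deadband))
  }
  c(RMS = sqrt(mean(x^2)),
    MAV = mean(abs(x)),
    WL = sum(abs(d)),
    ZC = zc,
    SSC = ssc,
    IEMG = sum(abs(x)))
}

# Welch power spectral density with Hamming windows, 50% overlap.
welch_psd <- function(x, fs, nwin = 128, overlap = 0.5) {
  n <- length(x)
  nwin <- min(nwin, n)
  step <- max(1L, round(nwin * (1 - overlap)))
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nwin) / (nwin - 1))
  starts <- seq(1L, n - nwin + 1L, by = step)
  nf <- floor(nwin / 2) + 1
  P <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1)]
    seg <- (seg - mean(seg)) * w
    P <- P + Mod(stats::fft(seg))[seq_len(nf)]^2
  }
  P <- P / length(starts)
  list(f = (seq_len(nf) - 1) * fs / nwin, P = P)
}

#' Frequency-domain sEMG features
#'
#' Welch periodogram; mean frequency `MNF = sum(f P(f)) / sum(P(f))` and
#' median frequency MDF (frequency splitting the spectral power in half).
#' An all-zero window yields NA (masked) features.
#'
#' @param x numeric vector (one channel, length >= 64).
#' @param fs sampling rate, Hz.
#' @param nwin Welch segment length in samples, default 128.
#' @return named numeric vector `MNF, MDF` (Hz).
#' @export
emg_freq_features <- function(x, fs, nwin = 128) {
  if (length(x) < 64) stop("window must have at least 64 samples")
  if (all(x == 0)) return(c(MNF = NA_real_, MDF = NA_real_))
  ps <- welch_psd(x, fs, nwin = nwin)
  tot <- sum(ps$P)
  mnf <- sum(ps$f * ps$P) / tot
  cum <- cumsum(ps$P) / tot
  mdf <- ps$f[which(cum >= 0.5)[1]]
  c(MNF = mnf, MDF = mdf)
}

#' Spectral slope of mean frequency across a segment
#'
#' Linear trend (Hz/s) of per-window MNF values, a fatigue indicator.
#'
#' @param mnf numeric vector of per-window mean frequencies, Hz.
#' @param t_center window centre times, seconds.
#' @return slope in Hz/s (NA with fewer than 3 windows).
#' @export
mnf_slope <- function(mnf, t_center) {
  ok <- is.finite(mnf)
  if (sum(ok) < 3) return(NA_real_)
  unname(stats::coef(stats::lm(mnf[ok] ~ t_center[ok]))[2])
}

#' Co-contraction index
#'
#' `CCI = sum(min(e_a, e_b)) / sum(max(e_a, e_b))` for two non-negative
#' activation envelopes; 1 for identical envelopes, 0 for disjoint support.
#' Returns NA (masked) when both envelopes are identically zero.
#'
#' @param e_a,e_b non-negative envelopes of equal length.
#' @return CCI in `[0, 1]` or NA.
#' @export
cci <- function(e_a, e_b) {
  stopifnot(length(e_a) == length(e_b))
  if (any(e_a < 0) || any(e_b < 0)) stop("envelopes must be non-negative")
  den <- sum(pmax(e_a, e_b))
  if (den == 0) return(NA_real_)
  sum(pmin(e_a, e_b)) / den
}

#' Electromechanical delay
#'
#' Motion onset minus EMG onset, seconds. Negative values (motion before
#' EMG) are allowed but flagged with a warning; a missing onset yields NA.
#'
#' @param emg_onset,motion_onset onset times in seconds (scalars, possibly
#'   NA).
#' @return delay in seconds or NA.
#' @export
emd_delay <- function(emg_onset, motion_onset) {
  if (is.na(emg_onset) || is.na(motion_onset)) return(NA_real_)
  d <- motion_onset - emg_onset
  if (d < 0) warning("negative electromechanical delay (motion before EMG)")
  d
}
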