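# Shared fixtures: small deterministic patients, trials and streams built
# in code at test time.

quiet_patient <- function(...) {
  args <- list(...)
  defaults <- list(capability = 0.5, rom_base = 60, tremor_amp = 0,
                   noise_sd = 0, cocontraction = 0)
  defaults[names(args)] <- args
  do.call(virtual_patient, defaults)
}

one_reach_trials <- function(duration = 4) {
  list(trial_spec(1, t_start = 1, t_end = 1 + duration,
                  distance_D = 30, width_W = 10))
}

# a settled-regime patient whose assistance fixed point is interior
responsive_patient <- function(noise_sd = 0) {
  virtual_patient(capability = 0.8, noise_sd = noise_sd)
}

# sinusoid stream helper
sine_stream <- function(freq, fs = 1000, dur = 2, amp = 1,
                        modality = "generic") {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  signal_stream(amp * sin(2 * pi * freq * tt), fs, modality = modality)
}

# power of x at frequency f via raw periodogram (brute-force oracle)
periodogram_power <- function(x, fs, f_lo, f_hi) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]^2
  fr <- (seq_along(P) - 1) * fs / n
  sum(P[fr >= f_lo & fr <= f_hi])
}
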