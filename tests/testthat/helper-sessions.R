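# Shared fixtures, generated in code. The "tiny" session keeps the protocol
# timing (10 s rest, >= 3 s wait) but only 4 trials x 2 cycles so unit tests
# stay fast; it is memoised across test files.

.fixtures <- new.env(parent = emptyenv())

tiny_protocol <- function(n_trials = 4, cycles_per_trial = 2) {
  default_protocol(n_trials = n_trials, cycles_per_trial = cycles_per_trial)
}

tiny_params <- function(seed = 42, erd_depth = 0.7,
                        channels = c("FC5", "FC1", "C3", "C1"),
                        band = c(8, 12), n_trials = 4, cycles_per_trial = 2,
                        ...) {
  synth_params(
    profile = subject_profile(channels = channels, band = band,
                              erd_depth = erd_depth, ...),
    protocol = tiny_protocol(n_trials, cycles_per_trial), seed = seed)
}

make_session <- function(params, subject_id = "test") {
  ses <- generate_session(params, subject_id)
  ses$events <- detect_real_starts(ses$imu, ses$events)
  ses
}

# high-SNR left-mu session reused by several files
shared_tiny_session <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- make_session(tiny_params())
  .fixtures$tiny
}

# independent band-power oracle: mean raw periodogram PSD over [lo, hi] Hz,
# computed directly from the DFT definition (no package code)
oracle_band_psd <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- abs(fft(x))^2 / (fs * n)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo - 1e-9 & f <= hi + 1e-9
  mean(2 * p[keep])
}

# DFT amplitude of a vector at one frequency
oracle_amp_at <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  2 * abs(sum(x * exp(-2i * pi * f * t))) / length(x)
}
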