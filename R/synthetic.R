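#' Synthetic subject profile
#'
#' Describes where and how strongly a synthetic subject expresses ERD/ERS:
#' band power over the affected channels is attenuated by a factor
#' `(1 - erd_depth)` (in amplitude) from `erd_onset_lead` seconds before the
#' movement onset up to the onset, and boosted by `(1 + ers_gain)` from the
#' onset for `ers_duration` seconds. All channels carry mu (10 Hz) and beta
#' (20 Hz) oscillations with random phase and a slowly fluctuating envelope on
#' top of 1/f-like background noise; on affected channels the oscillator
#' inside the affected band sits at the band's centre frequency.
#'
#' @param channels Affected channel subset (10-10 labels within the montage).
#' @param band Affected frequency band, Hz, within mu/beta (e.g. `c(8, 12)`).
#' @param erd_depth Fractional amplitude attenuation in \[0, 1\].
#' @param ers_gain Fractional rebound gain, >= 0.
#' @param erd_onset_lead Seconds before onset at which ERD begins (default 2).
#' @param ers_duration Seconds of post-onset ERS (default 2).
#' @param background_amp Background noise amplitude (standard deviation), uV.
#' @param rhythm_amp Rhythm oscillator amplitude per channel, uV.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(channels = c("FC5", "FC1", "C3", "C1"),
                            band = c(8, 12), erd_depth = 0.5, ers_gain = 0.5,
                            erd_onset_lead = 2, ers_duration = 2,
                            background_amp = 10, rhythm_amp = 10) {
  if (erd_depth < 0 || erd_depth > 1)
    stop("subject_profile: erd_depth must lie in [0, 1]")
  if (ers_gain < 0) stop("subject_profile: ers_gain must be >= 0")
  bad <- setdiff(channels, .MONTAGE_32)
  if (length(bad))
    stop("subject_profile: channels outside montage: ",
         paste(bad, collapse = ", "))
  structure(list(channels = channels, band = sort(band),
                 erd_depth = erd_depth, ers_gain = ers_gain,
                 erd_onset_lead = erd_onset_lead,
                 ers_duration = ers_duration,
                 background_amp = background_amp, rhythm_amp = rhythm_amp),
            class = "subject_profile")
}

#' Synthetic-session parameters
#'
#' @param profile A [subject_profile()].
#' @param protocol Protocol timing, see [default_protocol()].
#' @param line_noise_amp 50 Hz line-noise amplitude, uV (common to all
#'   channels).
#' @param imu_noise_sd IMU angular-velocity noise at rest, deg/s.
#' @param pedal_amp Pedaling angular-velocity amplitude, deg/s.
#' @param cadence_hz Pedaling cadence, Hz.
#' @param seed Integer RNG seed; a fixed seed yields an identical session.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(profile = subject_profile(),
                         protocol = default_protocol(), line_noise_amp = 2,
                         imu_noise_sd = 1, pedal_amp = 50, cadence_hz = 1,
                         seed = 1) {
  structure(list(profile = profile, protocol = protocol,
                 line_noise_amp = line_noise_amp, imu_noise_sd = imu_noise_sd,
                 pedal_amp = pedal_amp, cadence_hz = cadence_hz,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Run code with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# Approximate 1/f ("pink") noise: white noise through a cascade of three
# first-order recursive filters with staggered poles (Kellet-style pinking
# filter), normalised to unit standard deviation.
.pink_noise <- function(n) {
  p <- .pink_filter(rnorm(n))
  p / sd(p)
}

# Slowly varying (seconds-scale) unit-variance envelope fluctuation.
# Generated at 1/10 of the sampling rate and sample-held: the envelope's
# autocorrelation time (~1 s) is far above the 20 ms hold interval.
.slow_noise <- function(n) {
  m <- ceiling(n / 10)
  z <- .ar1_filter(rnorm(m), 0.998^10)
  z <- z / sd(z)
  rep(z, each = 10)[seq_len(n)]
}

#' Generate a synthetic session
#'
#' Emulates the cue-paced pedaling protocol: per cycle, `rest_s` seconds of
#' rest, a cue, a volitional wait drawn uniformly from \[3, 4.5\] s, then a
#' pedaling bout drawn uniformly from \[4.5, 5.5\] s (nominal `pedal_s` of
#' about 5 s). EEG (500 Hz, 32 channels, uV) carries 1/f-like background,
#' mu/beta oscillators with the profile's ERD/ERS modulation around each
#' movement onset, and common 50 Hz line noise. IMU traces (20 Hz, deg/s) are
#' near zero at rest and oscillate at `pedal_amp` on both legs while
#' pedaling. The true onsets are recorded in the event table.
#'
#' @param params A [synth_params()].
#' @param subject_id Subject identifier stored in the session.
#' @return A [bci_session()].
#' @export
generate_session <- function(params = synth_params(),
                             subject_id = "synthetic") {
  pr <- params$profile
  pp <- params$protocol
  n_cycles <- pp$n_trials * pp$cycles_per_trial
  fs <- 500
  fs_imu <- 20
  .with_seed(params$seed, {
    wait <- runif(n_cycles, 3, 4.5)
    pedal <- runif(n_cycles, pp$pedal_s - 0.5, pp$pedal_s + 0.5)
    dur <- pp$rest_s + wait + pedal
    # the 4 s rest class window reaches back to onset - 6.5 s and the wait
    # is at least 3 s, so the pre-cue rest must cover the remaining 3.5 s
    if (pp$rest_s < 3.5)
      stop("generate_session: rest period too short for the class windows")
    cyc_start <- cumsum(c(0, dur[-n_cycles]))
    cue <- cyc_start + pp$rest_s
    onset <- cue + wait
    cyc_end <- cyc_start + dur
    total <- cyc_end[n_cycles]

    ev <- event_table(trial = rep(seq_len(pp$n_trials),
                                  each = pp$cycles_per_trial),
                      cycle = rep(seq_len(pp$cycles_per_trial), pp$n_trials),
                      cycle_start_s = cyc_start, cycle_end_s = cyc_end,
                      cue_time_s = cue, real_start_time_s = onset,
                      discarded = FALSE)

    n <- as.integer(round(total * fs))
    t <- (seq_len(n) - 1) / fs

    # amplitude gain of the affected oscillator, per sample
    g <- rep(1, n)
    for (i in seq_len(n_cycles)) {
      e0 <- as.integer(round((onset[i] - pr$erd_onset_lead) * fs)) + 1L
      e1 <- as.integer(round(onset[i] * fs))
      s1 <- as.integer(round((onset[i] + pr$ers_duration) * fs))
      g[e0:e1] <- 1 - pr$erd_depth
      g[(e1 + 1L):s1] <- 1 + pr$ers_gain
    }

    centre <- mean(pr$band)
    mu_affected <- centre <= 14  # which oscillator carries the modulation
    line_phase <- runif(1, 0, 2 * pi)
    line <- params$line_noise_amp * sin(2 * pi * 50 * t + line_phase)

    X <- matrix(0, nrow = 32, ncol = n)
    for (c_i in seq_len(32)) {
      ch <- .MONTAGE_32[c_i]
      affected <- ch %in% pr$channels
      f_mu <- if (affected && mu_affected) centre else 10
      f_beta <- if (affected && !mu_affected) centre else 20
      env_mu <- pmax(1 + 0.3 * .slow_noise(n), 0)
      env_beta <- pmax(1 + 0.3 * .slow_noise(n), 0)
      if (affected) {
        if (mu_affected) env_mu <- env_mu * g else env_beta <- env_beta * g
      }
      X[c_i, ] <- pr$background_amp * .pink_noise(n) +
        pr$rhythm_amp * env_mu * sin(2 * pi * f_mu * t + runif(1, 0, 2 * pi)) +
        pr$rhythm_amp * env_beta *
          sin(2 * pi * f_beta * t + runif(1, 0, 2 * pi)) +
        line
    }
    eeg <- eeg_recording(.MONTAGE_32, fs, X)

    m <- as.integer(round(total * fs_imu))
    ti <- (seq_len(m) - 1) / fs_imu
    traces <- matrix(rnorm(4 * m, sd = params$imu_noise_sd), nrow = 4,
                     dimnames = list(.IMU_TRACES, NULL))
    sensor_phase <- c(0, pi / 2, pi, 3 * pi / 2)
    for (i in seq_len(n_cycles)) {
      idx <- which(ti >= onset[i] & ti < onset[i] + pedal[i])
      for (s in 1:4)
        traces[s, idx] <- traces[s, idx] + params$pedal_amp *
          sin(2 * pi * params$cadence_hz * (ti[idx] - onset[i]) +
                sensor_phase[s])
    }
    imu <- imu_recording(traces, fs_imu)

    bci_session(subject_id, eeg, imu, ev, pp)
  })
}

#' Generate a heterogeneous synthetic cohort
#'
#' Produces `n_subjects` parameter sets whose profiles rotate through
#' archetypes differing in spatial location (left motor, right motor,
#' midline) and band (mu, beta), so that different electrode configurations
#' are optimal for different synthetic subjects and personalization is
#' testable downstream.
#'
#' @param n_subjects Number of subjects, >= 1.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param erd_depth,ers_gain Shared modulation strengths.
#' @param protocol Protocol timing.
#' @return List of [synth_params()], one per subject, named `S1`, `S2`, ...
#' @export
generate_cohort <- function(n_subjects, seed = 1, erd_depth = 0.5,
                            ers_gain = 0.5, protocol = default_protocol()) {
  if (n_subjects < 1) stop("generate_cohort: n_subjects must be >= 1")
  left <- c("FC5", "FC1", "C3", "C1")
  right <- c("FC2", "FC6", "C2", "C4")
  midline <- c("C1", "CZ", "C2", "CP1", "CP2")
  mu <- c(8, 12)
  beta <- c(18, 24)
  archetypes <- list(list(left, mu), list(right, mu), list(left, beta),
                     list(right, beta), list(midline, mu))
  lapply(stats::setNames(seq_len(n_subjects),
                         paste0("S", seq_len(n_subjects))), function(i) {
    a <- archetypes[[(i - 1) %% length(archetypes) + 1]]
    sub_seed <- as.integer((as.numeric(seed) * 1009 + i * 101) %% 2147483647)
    synth_params(
      profile = subject_profile(channels = a[[1]], band = a[[2]],
                                erd_depth = erd_depth, ers_gain = ers_gain),
      protocol = protocol, seed = sub_seed)
  })
}
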