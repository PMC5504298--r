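test_that("a fixed seed reproduces the session exactly", {
  a <- generate_session(tiny_params(seed = 5))
  b <- generate_session(tiny_params(seed = 5))
  expect_identical(a$eeg$samples, b$eeg$samples)
  expect_identical(a$imu$traces, b$imu$traces)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  c <- generate_session(tiny_params(seed = 6))
  expect_false(identical(a$eeg$samples, c$eeg$samples))
})

test_that("signal lengths and protocol timing honour the event table", {
  ses <- generate_session(tiny_params(seed = 11))
  dur <- max(ses$events$cycle_end_s)
  expect_lte(abs(ncol(ses$eeg$samples) - dur * 500), 1)
  expect_lte(abs(ncol(ses$imu$traces) - dur * 20), 1)
  # volitional wait of at least 3 s on every cycle
  expect_true(all(ses$events$real_start_time_s - ses$events$cue_time_s >= 3))
  # waits are drawn from [3, 4.5]
  expect_true(all(ses$events$real_start_time_s - ses$events$cue_time_s <= 4.5))
})

test_that("IMU traces are quiet at rest and active while pedaling", {
  ses <- generate_session(tiny_params(seed = 12))
  ev <- ses$events
  fs <- ses$imu$sampling_rate
  t <- (seq_len(ncol(ses$imu$traces)) - 1) / fs
  rest_idx <- t >= ev$cycle_start_s[1] & t < ev$cue_time_s[1]
  pedal_idx <- t >= ev$real_start_time_s[1] + 0.1 &
    t < ev$real_start_time_s[1] + 2
  for (tr in rownames(ses$imu$traces)) {
    expect_lt(max(abs(ses$imu$traces[tr, rest_idx])), 10)
    expect_gt(max(abs(ses$imu$traces[tr, pedal_idx])), 25)
  }
})

test_that("band-power modulation matches the ERD depth and stays confined", {
  # 50 cycles; compare affected-band power in the 2 s before onset against a
  # 2 s mid-rest window, using a direct periodogram oracle on the raw EEG
  ratio_for <- function(erd_depth, channel) {
    p <- synth_params(
      profile = subject_profile(channels = c("FC5", "FC1", "C3", "C1"),
                                band = c(8, 12), erd_depth = erd_depth,
                                ers_gain = 0),
      protocol = default_protocol(n_trials = 10, cycles_per_trial = 5),
      seed = 303)
    ses <- generate_session(p)
    row <- match(channel, ses$eeg$channel_names)
    fs <- ses$eeg$sampling_rate
    # rhythm band power corrected for the 1/f noise floor, which is
    # estimated from flanking bands clear of the AM sidebands
    corrected <- function(x) {
      floor_est <- (oracle_band_psd(x, fs, 5.5, 7.5) +
                      oracle_band_psd(x, fs, 12.5, 14.5)) / 2
      oracle_band_psd(x, fs, 9, 11) - floor_est
    }
    num <- den <- numeric(nrow(ses$events))
    for (i in seq_len(nrow(ses$events))) {
      on <- ses$events$real_start_time_s[i]
      cs <- ses$events$cycle_start_s[i]
      pre <- ses$eeg$samples[row, round((on - 2) * fs):(round(on * fs) - 1)]
      mid <- ses$eeg$samples[row, round((cs + 4) * fs):
                                    (round((cs + 6) * fs) - 1)]
      num[i] <- corrected(pre)
      den[i] <- corrected(mid)
    }
    mean(num) / mean(den)
  }
  # null effect: no modulation, ratio ~ 1 up to sampling error
  expect_lt(abs(ratio_for(0, "C3") - 1), 0.1)
  # amplitude factor 0.5 -> band-power factor 0.25
  expect_lt(abs(ratio_for(0.5, "C3") - 0.25), 0.05)
  # unaffected channel passes the null-effect check at full modulation
  expect_lt(abs(ratio_for(0.5, "C4") - 1), 0.1)
})

test_that("cohorts are reproducible and heterogeneous", {
  a <- generate_cohort(5, seed = 77)
  b <- generate_cohort(5, seed = 77)
  expect_identical(a, b)
  expect_named(a, paste0("S", 1:5))
  chans <- lapply(a, function(p) p$profile$channels)
  bands <- lapply(a, function(p) p$profile$band)
  expect_gt(length(unique(chans)), 1)
  expect_gt(length(unique(bands)), 1)
  expect_length(generate_cohort(1, seed = 1), 1)
  expect_error(generate_cohort(0), ">= 1")
})
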