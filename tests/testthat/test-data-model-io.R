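test_that("session directory round-trips all fields", {
  ses <- make_session(tiny_params(seed = 7, n_trials = 1))
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  expect_true(all(file.exists(file.path(dir, c("meta.json", "eeg.tsv",
                                               "imu.tsv", "events.tsv")))))
  back <- read_session(dir)
  expect_identical(back$subject_id, ses$subject_id)
  expect_identical(back$eeg$channel_names, ses$eeg$channel_names)
  expect_equal(back$eeg$sampling_rate, ses$eeg$sampling_rate)
  expect_equal(back$eeg$samples, ses$eeg$samples, tolerance = 1e-9)
  expect_equal(back$imu$traces, ses$imu$traces, tolerance = 1e-9)
  expect_equal(as.data.frame(back$events), as.data.frame(ses$events),
               tolerance = 1e-9)
  expect_equal(back$protocol, ses$protocol)
})

test_that("a discarded cycle and its reason are persisted", {
  ses <- make_session(tiny_params(seed = 8, n_trials = 1))
  ses$events$discarded[2] <- TRUE
  ses$events$discard_reason[2] <- "no onset"
  ses$events$real_start_time_s[2] <- NA_real_
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  back <- read_session(dir)
  expect_true(back$events$discarded[2])
  expect_identical(back$events$discard_reason[2], "no onset")
})

test_that("data-model invariants are enforced", {
  # channel-count mismatch
  expect_error(eeg_recording(c("C3", "C4"), 500, matrix(0, 3, 10)),
               "does not match")
  expect_error(eeg_recording(c("C3", "C3"), 500, matrix(0, 2, 10)), "unique")
  expect_error(eeg_recording("C3", 0, matrix(0, 1, 10)), "positive")
  # onset earlier than 3 s after cue on a non-discarded cycle
  expect_error(event_table(1, 1, 0, 20, 10, real_start_time_s = 12,
                           discarded = FALSE), "3 s after cue")
  # cue before cycle start
  expect_error(event_table(1, 1, 5, 20, 3), "cue before cycle start")
  # IMU shape
  expect_error(imu_recording(matrix(0, 3, 10)), "4 rows")
})

test_that("the reader rejects sessions mutated into invalid states", {
  ses <- make_session(tiny_params(seed = 9, n_trials = 1))
  dir <- withr::local_tempdir()
  write_session(ses, dir)

  # declared sampling rate disagreeing with the sample spacing
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  meta$eeg_sampling_rate_hz <- 250
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_session(dir), "disagrees")

  # onset pulled before the cue + 3 s bound
  write_session(ses, dir)
  ev <- data.table::fread(file.path(dir, "events.tsv"))
  ev$real_start_time_s[1] <- ev$cue_time_s[1] + 1
  data.table::fwrite(ev, file.path(dir, "events.tsv"), sep = "\t")
  expect_error(read_session(dir), "3 s after cue")

  # missing component file
  write_session(ses, dir)
  unlink(file.path(dir, "imu.tsv"))
  expect_error(read_session(dir), "missing")
})

test_that("EDF import recovers labels, rate and calibrated samples", {
  # reference writer: builds a toy 3-channel EDF directly from the format
  # definition (ASCII headers + int16 little-endian records)
  write_toy_edf <- function(path, labels, fs, data, phys_range = 200) {
    ns <- length(labels)
    n_rec <- ncol(data) / fs
    pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                  pad("01.01.20", 8), pad("00.00.00", 8),
                  pad(256 + 256 * ns, 8), pad("", 44), pad(n_rec, 8),
                  pad(1, 8), pad(ns, 4))
    sig <- paste0(
      paste(vapply(labels, pad, "", w = 16), collapse = ""),
      paste(rep(pad("", 80), ns), collapse = ""),
      paste(rep(pad("uV", 8), ns), collapse = ""),
      paste(rep(pad(-phys_range, 8), ns), collapse = ""),
      paste(rep(pad(phys_range, 8), ns), collapse = ""),
      paste(rep(pad(-32768, 8), ns), collapse = ""),
      paste(rep(pad(32767, 8), ns), collapse = ""),
      paste(rep(pad("", 80), ns), collapse = ""),
      paste(rep(pad(fs, 8), ns), collapse = ""),
      paste(rep(pad("", 32), ns), collapse = ""))
    writeChar(paste0(hdr, sig), con, eos = NULL)
    gain <- (2 * phys_range) / (32767 - (-32768))
    for (r in seq_len(n_rec)) for (s in seq_len(ns)) {
      seg <- data[s, (r - 1) * fs + seq_len(fs)]
      dig <- as.integer(round((seg - (-phys_range)) / gain)) - 32768L
      writeBin(dig, con, size = 2, endian = "little")
    }
  }

  labels <- c("C3", "CZ", "C4")
  fs <- 100
  set.seed(1)
  data <- matrix(round(rnorm(3 * 200, sd = 30), 1), nrow = 3)
  path <- withr::local_tempfile(fileext = ".edf")
  write_toy_edf(path, labels, fs, data)

  rec <- read_edf_eeg(path)
  expect_s3_class(rec, "eeg_recording")
  expect_identical(rec$channel_names, labels)
  expect_equal(rec$sampling_rate, fs)
  # 16-bit quantisation step of a +/-200 uV range is ~0.006 uV
  expect_equal(rec$samples, data, tolerance = 0.01, ignore_attr = TRUE)
})
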