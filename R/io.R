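#' Write a session to a directory
#'
#' Canonical on-disk format: a directory holding `meta.json` (subject, rates,
#' units, protocol), `eeg.tsv` (`time_s` plus one column per channel, in
#' microvolts), `imu.tsv` (`time_s`, `left_ankle`, `left_tibialis`,
#' `right_ankle`, `right_tibialis`, in deg/s) and `events.tsv`. All times are
#' seconds from session start; intervals are half-open `[start, end)`.
#'
#' @param session A valid [bci_session()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("write_session: cannot create ", path)

  meta <- list(
    subject_id = session$subject_id,
    eeg_sampling_rate_hz = session$eeg$sampling_rate,
    eeg_start_time_s = session$eeg$start_time,
    eeg_unit = "uV",
    imu_sampling_rate_hz = session$imu$sampling_rate,
    imu_start_time_s = session$imu$start_time,
    imu_unit = "deg/s",
    protocol = session$protocol
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  eeg <- session$eeg
  n <- ncol(eeg$samples)
  eeg_df <- data.table::data.table(
    time_s = eeg$start_time + (seq_len(n) - 1) / eeg$sampling_rate)
  for (i in seq_along(eeg$channel_names))
    data.table::set(eeg_df, j = eeg$channel_names[i], value = eeg$samples[i, ])
  data.table::fwrite(eeg_df, file.path(path, "eeg.tsv"), sep = "\t")

  imu <- session$imu
  m <- ncol(imu$traces)
  imu_df <- data.table::data.table(
    time_s = imu$start_time + (seq_len(m) - 1) / imu$sampling_rate)
  for (nm in rownames(imu$traces))
    data.table::set(imu_df, j = nm, value = imu$traces[nm, ])
  data.table::fwrite(imu_df, file.path(path, "imu.tsv"), sep = "\t")

  data.table::fwrite(as.data.frame(session$events),
                     file.path(path, "events.tsv"), sep = "\t")
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]; the returned session equals the written one
#' up to float-text round-trip precision and is re-validated against all
#' data-model invariants.
#'
#' @param path Session directory.
#' @return A [bci_session()].
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("read_session: missing ", meta_file)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (f in c("eeg.tsv", "imu.tsv", "events.tsv"))
    if (!file.exists(file.path(path, f)))
      stop("read_session: missing ", file.path(path, f))

  eeg_df <- data.table::fread(file.path(path, "eeg.tsv"), sep = "\t")
  if (names(eeg_df)[1] != "time_s") stop("read_session: malformed eeg.tsv header")
  ch <- names(eeg_df)[-1]
  samples <- t(as.matrix(eeg_df[, -1, with = FALSE]))
  dimnames(samples) <- NULL
  if (nrow(eeg_df) >= 2) {
    dt <- diff(eeg_df$time_s[1:2])
    if (abs(1 / dt - meta$eeg_sampling_rate_hz) > 1e-3 * meta$eeg_sampling_rate_hz)
      stop("read_session: eeg.tsv sample spacing disagrees with declared rate")
  }
  eeg <- eeg_recording(ch, meta$eeg_sampling_rate_hz, samples,
                       meta$eeg_start_time_s)

  imu_df <- data.table::fread(file.path(path, "imu.tsv"), sep = "\t")
  traces <- t(as.matrix(imu_df[, .IMU_TRACES, with = FALSE]))
  imu <- imu_recording(traces, meta$imu_sampling_rate_hz, meta$imu_start_time_s)

  ev_df <- data.table::fread(file.path(path, "events.tsv"), sep = "\t")
  if (!"discard_reason" %in% names(ev_df)) ev_df$discard_reason <- ""
  ev_df$discard_reason[is.na(ev_df$discard_reason)] <- ""
  ev <- event_table(ev_df$trial, ev_df$cycle, ev_df$cycle_start_s,
                    ev_df$cycle_end_s, ev_df$cue_time_s,
                    ev_df$real_start_time_s, ev_df$discarded,
                    ev_df$discard_reason)

  proto <- meta$protocol
  bci_session(meta$subject_id, eeg, imu, ev,
              default_protocol(proto$n_trials, proto$cycles_per_trial,
                               proto$rest_s, proto$pedal_s))
}

#' Import EEG from an EDF file
#'
#' Minimal reader for uncompressed EDF (European Data Format): parses the
#' 256-byte fixed header, the per-signal header block, and the 16-bit
#' little-endian data records, applying the per-signal digital-to-physical
#' calibration. All signals must share one sampling rate. This import is a
#' convenience; the canonical session format is the TSV directory of
#' [write_session()].
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] (units as stored in the file, assumed uV).
#' @export
read_edf_eeg <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fld <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- fld(8)
  if (version != "0") stop("read_edf_eeg: unsupported EDF version '", version, "'")
  fld(80); fld(80); fld(8); fld(8)          # patient, recording, date, time
  header_bytes <- as.integer(fld(8))
  fld(44)                                   # reserved
  n_records <- as.integer(fld(8))
  record_dur <- as.numeric(fld(8))
  ns <- as.integer(fld(4))
  if (is.na(ns) || ns < 1) stop("read_edf_eeg: malformed header (no signals)")

  sig_fld <- function(n) vapply(seq_len(ns), function(i) fld(n), character(1))
  labels <- sig_fld(16)
  sig_fld(80); sig_fld(8)                   # transducer, physical dimension
  phys_min <- as.numeric(sig_fld(8)); phys_max <- as.numeric(sig_fld(8))
  dig_min <- as.numeric(sig_fld(8));  dig_max <- as.numeric(sig_fld(8))
  sig_fld(80)                               # prefiltering
  nsamp <- as.integer(sig_fld(8))
  sig_fld(32)                               # reserved
  if (length(unique(nsamp)) != 1)
    stop("read_edf_eeg: signals with differing rates are not supported")
  expected_header <- 256L + 256L * ns
  if (!is.na(header_bytes) && header_bytes != expected_header)
    stop("read_edf_eeg: malformed header (byte count)")

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- matrix(0, nrow = ns, ncol = n_records * nsamp[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = nsamp[1], size = 2, endian = "little")
      out[s, (r - 1) * nsamp[1] + seq_len(nsamp[1])] <-
        gain[s] * d + offset[s]
    }
  }
  eeg_recording(labels, nsamp[1] / record_dur, out)
}
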