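#' EEG recording
#'
#' Container for a multichannel EEG block: a channels x time matrix in
#' microvolts plus channel labels and the sampling rate.
#'
#' @param channel_names Character vector of unique 10-10 labels, one per row
#'   of `samples`.
#' @param sampling_rate Sampling rate in Hz (default protocol: 500).
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param start_time Time of the first sample in seconds from session start.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(channel_names, sampling_rate, samples,
                          start_time = 0) {
  samples <- as.matrix(samples)
  x <- structure(
    list(channel_names = as.character(channel_names),
         sampling_rate = as.numeric(sampling_rate),
         samples = samples,
         start_time = as.numeric(start_time)),
    class = "eeg_recording"
  )
  validate_eeg_recording(x)
  x
}

validate_eeg_recording <- function(x) {
  if (!is.numeric(x$sampling_rate) || length(x$sampling_rate) != 1 ||
      x$sampling_rate <= 0)
    stop("eeg_recording: sampling_rate must be a single positive number")
  if (length(x$channel_names) != nrow(x$samples))
    stop("eeg_recording: number of channel names (", length(x$channel_names),
         ") does not match matrix row count (", nrow(x$samples), ")")
  if (anyDuplicated(x$channel_names))
    stop("eeg_recording: channel names must be unique")
  invisible(x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  invisible(x)
}

.IMU_TRACES <- c("left_ankle", "left_tibialis", "right_ankle", "right_tibialis")

#' IMU recording
#'
#' Angular-velocity traces (gyroscope X axis, deg/s) from two inertial sensors
#' per leg: ankle and tibialis anterior, left and right.
#'
#' @param traces Numeric matrix with 4 rows named `left_ankle`,
#'   `left_tibialis`, `right_ankle`, `right_tibialis`.
#' @param sampling_rate Sampling rate in Hz (default 20).
#' @param start_time Time of the first sample in seconds from session start.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(traces, sampling_rate = 20, start_time = 0) {
  traces <- as.matrix(traces)
  x <- structure(
    list(traces = traces, sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time)),
    class = "imu_recording"
  )
  validate_imu_recording(x)
  x
}

validate_imu_recording <- function(x) {
  if (x$sampling_rate <= 0)
    stop("imu_recording: sampling_rate must be positive")
  if (nrow(x$traces) != 4 || !identical(rownames(x$traces), .IMU_TRACES))
    stop("imu_recording: traces must have 4 rows named ",
         paste(.IMU_TRACES, collapse = ", "))
  invisible(x)
}

#' Event table
#'
#' Per-cycle protocol events: trial and cycle indices, cycle boundaries, the
#' experimenter cue, the detected (or generator-known) movement onset, and a
#' discarded flag for cycles where the subject moved less than 3 s after the
#' cue (or no onset was found).
#'
#' @param trial,cycle Integer indices.
#' @param cycle_start_s,cycle_end_s Cycle boundaries, seconds from session
#'   start (half-open interval).
#' @param cue_time_s Cue time, seconds.
#' @param real_start_time_s Movement onset, seconds; `NA` until detected.
#' @param discarded Logical flag.
#' @param discard_reason Optional character reason (`""` when not discarded).
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(trial, cycle, cycle_start_s, cycle_end_s, cue_time_s,
                        real_start_time_s = NA_real_, discarded = FALSE,
                        discard_reason = "") {
  df <- data.frame(trial = as.integer(trial), cycle = as.integer(cycle),
                   cycle_start_s = as.numeric(cycle_start_s),
                   cycle_end_s = as.numeric(cycle_end_s),
                   cue_time_s = as.numeric(cue_time_s),
                   real_start_time_s = as.numeric(real_start_time_s),
                   discarded = as.logical(discarded),
                   discard_reason = as.character(discard_reason))
  class(df) <- c("event_table", "data.frame")
  validate_event_table(df)
  df
}

validate_event_table <- function(ev) {
  if (any(ev$cue_time_s < ev$cycle_start_s, na.rm = TRUE))
    stop("event_table: cue before cycle start")
  for (tr in unique(ev$trial)) {
    ct <- ev$cue_time_s[ev$trial == tr]
    if (is.unsorted(ct, strictly = FALSE))
      stop("event_table: cue times not nondecreasing within trial ", tr)
  }
  ok <- !ev$discarded & !is.na(ev$real_start_time_s)
  if (any(ev$real_start_time_s[ok] < ev$cue_time_s[ok] + 3))
    stop("event_table: non-discarded cycle with onset < 3 s after cue")
  invisible(ev)
}

#' Default protocol parameters
#'
#' The cue-paced pedaling protocol: 16 trials of 5 cycles; each cycle is about
#' 10 s of rest, a cue, a volitional wait of at least 3 s, then about 5 s of
#' pedaling.
#'
#' @param n_trials Number of trials per session.
#' @param cycles_per_trial Pedaling cycles per trial.
#' @param rest_s Resting period preceding the cue, seconds.
#' @param pedal_s Nominal pedaling duration, seconds.
#' @return A named list of protocol parameters.
#' @export
default_protocol <- function(n_trials = 16, cycles_per_trial = 5, rest_s = 10,
                             pedal_s = 5) {
  list(n_trials = as.integer(n_trials),
       cycles_per_trial = as.integer(cycles_per_trial),
       rest_s = as.numeric(rest_s), pedal_s = as.numeric(pedal_s))
}

#' Recording session
#'
#' One subject's session: EEG, IMU, event table and protocol metadata.
#'
#' @param subject_id Character subject identifier.
#' @param eeg An [eeg_recording()].
#' @param imu An [imu_recording()].
#' @param events An [event_table()].
#' @param protocol Protocol parameters, see [default_protocol()].
#' @return An object of class `bci_session`.
#' @export
bci_session <- function(subject_id, eeg, imu, events,
                        protocol = default_protocol()) {
  x <- structure(
    list(subject_id = as.character(subject_id), eeg = eeg, imu = imu,
         events = events, protocol = protocol),
    class = "bci_session"
  )
  validate_session(x)
  x
}

#' Validate a session against the data-model invariants
#'
#' @param x A `bci_session`.
#' @return The session, invisibly; errors on any invariant violation.
#' @export
validate_session <- function(x) {
  stopifnot(inherits(x, "bci_session"))
  validate_eeg_recording(x$eeg)
  validate_imu_recording(x$imu)
  validate_event_table(x$events)
  if (nrow(x$events) != x$protocol$n_trials * x$protocol$cycles_per_trial)
    stop("session: event table has ", nrow(x$events),
         " cycles but protocol declares ",
         x$protocol$n_trials * x$protocol$cycles_per_trial)
  invisible(x)
}

#' @export
print.bci_session <- function(x, ...) {
  cat(sprintf(
    "<bci_session> subject %s: %d trials x %d cycles, %d discarded\n",
    x$subject_id, x$protocol$n_trials, x$protocol$cycles_per_trial,
    sum(x$events$discarded)))
  print(x$eeg)
  invisible(x)
}
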