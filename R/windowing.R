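#' EEG epoch
#'
#' The atomic classification unit: a short slice of multichannel EEG.
#'
#' @param samples Channels x samples numeric matrix.
#' @param channel_names Channel labels, one per row.
#' @param sampling_rate Hz.
#' @param start_time Epoch start, seconds from session start.
#' @return An object of class `eeg_epoch`.
#' @export
epoch <- function(samples, channel_names, sampling_rate, start_time = 0) {
  samples <- as.matrix(samples)
  if (length(channel_names) != nrow(samples))
    stop("epoch: channel names do not match matrix rows")
  structure(list(samples = samples,
                 channel_names = as.character(channel_names),
                 sampling_rate = as.numeric(sampling_rate),
                 start_time = as.numeric(start_time)),
            class = "eeg_epoch")
}

#' Build the rest and start class windows around a movement onset
#'
#' For 4 s processing windows the start class spans 2 s before to 2 s after
#' the onset; for 2 s windows it spans the 2 s before the onset. The rest
#' class window has the same duration and precedes the start window with a
#' 0.5 s gap. Intervals are half-open `[t0, t1)`.
#'
#' @param onset_time Movement onset, seconds.
#' @param window_type `"4s"` or `"2s"`.
#' @param cycle_start Optional cycle start time; if given, an error is raised
#'   when the rest window would extend before it.
#' @return List with elements `rest` and `start`, each a list
#'   `(label, t0, t1)`.
#' @export
build_class_windows <- function(onset_time, window_type = c("4s", "2s"),
                                cycle_start = NULL) {
  window_type <- match.arg(window_type)
  if (window_type == "4s") {
    start <- c(onset_time - 2, onset_time + 2)
    rest <- c(onset_time - 6.5, onset_time - 2.5)
  } else {
    start <- c(onset_time - 2, onset_time)
    rest <- c(onset_time - 4.5, onset_time - 2.5)
  }
  if (!is.null(cycle_start) && rest[1] < cycle_start)
    stop("build_class_windows: insufficient rest before onset")
  list(rest = list(label = "rest", t0 = rest[1], t1 = rest[2]),
       start = list(label = "start", t0 = start[1], t1 = start[2]))
}

#' Window length in seconds for a window type
#' @param window_type `"4s"` or `"2s"`.
#' @return 4 or 2.
#' @export
window_length_s <- function(window_type = c("4s", "2s")) {
  switch(match.arg(window_type), "4s" = 4, "2s" = 2)
}

#' Epochs per class window at the default epoching
#' @param window_type `"4s"` or `"2s"`.
#' @param epoch_length,shift Epoching parameters, seconds.
#' @return Number of epochs fitting in the window (16 for 4 s, 6 for 2 s).
#' @export
epochs_per_window <- function(window_type = c("4s", "2s"), epoch_length = 1,
                              shift = 0.2) {
  L <- window_length_s(match.arg(window_type))
  # computed on an integer grid to avoid float division artefacts
  .n_epochs(round(L * 1000), round(epoch_length * 1000), round(shift * 1000))
}

.n_epochs <- function(L, ep, sh) {
  if (L < ep) 0L else as.integer((L - ep) %/% sh + 1L)
}

#' Slice an interval of a recording into overlapping epochs
#'
#' Epochs of `epoch_length` seconds start at `t0, t0 + shift, ...` and must
#' lie fully inside the half-open interval. Epoch boundaries are snapped to
#' the sample grid (fractional sample counts round down).
#'
#' @param eeg An [eeg_recording()].
#' @param interval Numeric `c(t0, t1)`, seconds, half-open.
#' @param epoch_length Epoch duration, seconds (default 1).
#' @param shift Step between epoch starts, seconds (default 0.2).
#' @return List of [epoch()] objects (empty when the interval is shorter than
#'   one epoch).
#' @export
slice_epochs <- function(eeg, interval, epoch_length = 1, shift = 0.2) {
  if (shift <= 0) stop("slice_epochs: shift must be positive")
  fs <- eeg$sampling_rate
  i0 <- as.integer(ceiling(round((interval[1] - eeg$start_time) * fs, 6)))
  L <- as.integer(floor(round((interval[2] - interval[1]) * fs, 6)))
  ep <- as.integer(round(epoch_length * fs))
  sh <- as.integer(round(shift * fs))
  over <- i0 + L - ncol(eeg$samples)
  if (i0 < 0 || over > 2)  # tolerate float rounding at the recording edge
    stop("slice_epochs: interval outside recording")
  if (over > 0) L <- L - over
  n <- .n_epochs(L, ep, sh)
  if (n <= 0) return(list())
  lapply(seq_len(n), function(k) {
    off <- i0 + (k - 1L) * sh
    epoch(eeg$samples[, off + seq_len(ep), drop = FALSE], eeg$channel_names,
          fs, eeg$start_time + off / fs)
  })
}
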