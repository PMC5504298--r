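#' Detect real movement onsets from IMU angular velocities
#'
#' For each cycle, the two sensor traces of each leg are averaged and the real
#' start is the earliest IMU sample at or after the cue where the absolute
#' averaged angular velocity of *both* legs exceeds the threshold. Cycles
#' where no crossing occurs before the cycle end are flagged discarded with
#' reason `"no onset"`; cycles whose onset falls less than 3 s after the cue
#' are flagged discarded with reason `"moved early"` (the volitional-wait
#' requirement). Onset resolution is the IMU sampling grid; no interpolation.
#'
#' @param imu An [imu_recording()].
#' @param events An [event_table()] with cue times and cycle boundaries.
#' @param threshold Angular-velocity threshold, deg/s (> 0; default 10).
#' @param min_wait_s Minimum cue-to-onset wait, seconds (default 3).
#' @return The event table with `real_start_time_s`, `discarded` and
#'   `discard_reason` filled in; all other fields preserved.
#' @export
detect_real_starts <- function(imu, events, threshold = 10, min_wait_s = 3) {
  if (threshold <= 0) stop("detect_real_starts: threshold must be > 0")
  fs <- imu$sampling_rate
  n <- ncol(imu$traces)
  times <- imu$start_time + (seq_len(n) - 1) / fs
  left <- abs(colMeans(imu$traces[c("left_ankle", "left_tibialis"), ,
                                  drop = FALSE]))
  right <- abs(colMeans(imu$traces[c("right_ankle", "right_tibialis"), ,
                                   drop = FALSE]))
  both <- left > threshold & right > threshold

  ev <- events
  for (i in seq_len(nrow(ev))) {
    win <- which(times >= ev$cue_time_s[i] & times < ev$cycle_end_s[i])
    if (length(win) == 0)
      stop("detect_real_starts: IMU does not cover cycle ", i)
    hit <- win[both[win]]
    if (length(hit) == 0) {
      ev$real_start_time_s[i] <- NA_real_
      ev$discarded[i] <- TRUE
      ev$discard_reason[i] <- "no onset"
    } else {
      t0 <- times[hit[1]]
      ev$real_start_time_s[i] <- t0
      if (t0 - ev$cue_time_s[i] < min_wait_s) {
        ev$discarded[i] <- TRUE
        ev$discard_reason[i] <- "moved early"
      } else {
        ev$discarded[i] <- FALSE
        ev$discard_reason[i] <- ""
      }
    }
  }
  validate_event_table(ev)
  ev
}
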