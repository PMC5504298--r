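#' Weighting scheme of the weighted discriminator
#'
#' WD = 0.4 TPR + 0.6 Acc - 1.0 FPR, with FPR = (FP/min) x (duration of one
#' false positive in minutes). That duration is the processing-window length
#' (2 or 4 s) for the offline analysis and 1 s (five consecutive 200 ms
#' epoch shifts) for the pseudo-online analysis.
#'
#' @param mode `"offline"` or `"pseudo-online"`.
#' @param window_type `"4s"` or `"2s"` (used in offline mode).
#' @return List of weights and the FP duration in minutes.
#' @export
wd_weights <- function(mode = c("offline", "pseudo-online"),
                       window_type = c("4s", "2s")) {
  mode <- match.arg(mode)
  fp_dur <- if (mode == "offline")
    window_length_s(match.arg(window_type)) / 60 else 1 / 60
  list(w_tpr = 0.4, w_acc = 0.6, w_fpr = 1.0, fp_duration_min = fp_dur)
}

#' Detection-count metrics
#'
#' TPR = true detections / true events; FP/min = false detections / rest time
#' in minutes; Acc = true detections / all detections (0 when there are no
#' detections at all).
#'
#' @param n_true_det,n_true_events,n_false_det Nonnegative counts.
#' @param rest_time_min Rest time in minutes, > 0.
#' @return List `(tpr, fp_per_min, acc)`; `tpr` and `acc` are fractions.
#' @export
compute_counts_metrics <- function(n_true_det, n_true_events, n_false_det,
                                   rest_time_min) {
  if (any(c(n_true_det, n_true_events, n_false_det) < 0))
    stop("compute_counts_metrics: negative counts")
  if (n_true_events < 1) stop("compute_counts_metrics: no true events")
  if (rest_time_min <= 0) stop("compute_counts_metrics: rest time must be > 0")
  total <- n_true_det + n_false_det
  list(tpr = n_true_det / n_true_events,
       fp_per_min = n_false_det / rest_time_min,
       acc = if (total == 0) 0 else n_true_det / total)
}

#' Weighted discriminator
#'
#' @param tpr,acc Fractions in \[0, 1\].
#' @param fp_per_min False positives per minute.
#' @param weights A [wd_weights()] object fixing the FP duration.
#' @return WD value in \[-1, 1\] whenever FPR is in \[0, 1\].
#' @export
compute_wd <- function(tpr, acc, fp_per_min, weights = wd_weights()) {
  if (any(!is.finite(c(tpr, acc, fp_per_min))))
    stop("compute_wd: inputs must be finite")
  fpr <- fp_per_min * weights$fp_duration_min
  weights$w_tpr * tpr + weights$w_acc * acc - weights$w_fpr * fpr
}

#' Round half away from zero
#'
#' Rounding convention used when comparing against 2-decimal printed values
#' (base `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assemble an evaluation result
#'
#' @param tpr,fp_per_min,acc Averaged metrics (fractions for tpr/acc).
#' @param weights A [wd_weights()].
#' @param counts Optional underlying counts (kept for audit).
#' @param per_split Optional per-fold / per-trial metric data.frame.
#' @return Object of class `evaluation_result` with fields `tpr`,
#'   `fp_per_min`, `acc`, `fpr`, `wd`.
#' @export
evaluation_result <- function(tpr, fp_per_min, acc, weights, counts = NULL,
                              per_split = NULL) {
  structure(list(tpr = tpr, fp_per_min = fp_per_min, acc = acc,
                 fpr = fp_per_min * weights$fp_duration_min,
                 wd = compute_wd(tpr, acc, fp_per_min, weights),
                 weights = weights, counts = counts, per_split = per_split),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> TPR %.1f%%  FP/min %.2f  Acc %.1f%%  WD %.2f\n",
              100 * x$tpr, x$fp_per_min, 100 * x$acc, x$wd))
  invisible(x)
}

#' Flatten an evaluation result for TSV/JSON export
#' @param x An [evaluation_result()].
#' @return One-row data.frame with `tpr_pct`, `fp_per_min`, `acc_pct`, `fpr`,
#'   `wd`.
#' @export
as_result_row <- function(x) {
  data.frame(tpr_pct = 100 * x$tpr, fp_per_min = x$fp_per_min,
             acc_pct = 100 * x$acc, fpr = x$fpr, wd = x$wd)
}
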