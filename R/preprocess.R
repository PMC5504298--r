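#' Per-epoch filter specification
#'
#' Signal conditioning applied to every epoch before channel selection, in
#' this order: 50 Hz notch (2nd-order IIR, quality factor `notch_q`), 4th
#' order Butterworth high-pass at `hp_cutoff_hz` to remove the DC drift, and
#' a common average reference (CAR) subtracting the instantaneous mean across
#' all recorded channels from each channel. Both IIR filters are applied
#' zero-phase (forward-backward) so that ERD/ERS timing is not shifted by
#' group delay.
#'
#' @param notch_hz Power-line frequency to suppress, Hz.
#' @param notch_q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @param hp_order Butterworth high-pass order (even).
#' @param hp_cutoff_hz High-pass cutoff, Hz.
#' @param car Logical; apply the common average reference.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = 50, notch_q = 10, hp_order = 4,
                        hp_cutoff_hz = 0.2, car = TRUE) {
  if (hp_order %% 2 != 0) stop("filter_spec: hp_order must be even")
  structure(list(notch_hz = notch_hz, notch_q = notch_q, hp_order = hp_order,
                 hp_cutoff_hz = hp_cutoff_hz, car = car),
            class = "filter_spec")
}

# Steady-state (step-input) initial filter state for a direct-form II
# transposed IIR filter, per unit input amplitude.
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  # companion matrix of a, transposed
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(n - 1) - t(comp), B))
}

# Filter designs for a given sampling rate.
.design_filters <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$hp_cutoff_hz >= nyq) stop("filter_spec: cutoff must be < Nyquist")
  # RBJ-cookbook biquad notch, unit gain at DC and Nyquist
  w0 <- 2 * pi * spec$notch_hz / fs
  alpha <- sin(w0) / (2 * spec$notch_q)
  a0 <- 1 + alpha
  notch_b <- c(1, -2 * cos(w0), 1) / a0
  notch_a <- c(1, -2 * cos(w0) / a0, (1 - alpha) / a0)
  hp <- signal::butter(spec$hp_order, spec$hp_cutoff_hz / nyq, type = "high")
  list(
    notch = list(b = notch_b, a = notch_a, zi = .lfilter_zi(notch_b, notch_a),
                 npad = 3L * (length(notch_a) - 1L)),
    hp = list(b = hp$b, a = hp$a, zi = .lfilter_zi(hp$b, hp$a),
              npad = 3L * (length(hp$a) - 1L))
  )
}

#' Zero-phase IIR filtering of a multichannel matrix
#'
#' Forward-backward filtering of each row (channel) with odd-symmetric edge
#' extension and steady-state initial conditions, so constant signals incur no
#' edge transient.
#'
#' @param b,a Filter coefficients (`a[1]` is normalised to 1).
#' @param x Channels x samples numeric matrix (a plain vector is treated as a
#'   single channel).
#' @return Filtered matrix (or vector) of the same shape.
#' @export
zerophase_filter <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  b <- b / a[1]; a <- a / a[1]
  zi <- .lfilter_zi(b, a)
  out <- .filtfilt_mat(b, a, zi, x, 3L * (max(length(a), length(b)) - 1L))
  if (vec) drop(out) else out
}

#' Common average reference
#'
#' Subtracts, at each sample, the mean across all channels from every channel.
#'
#' @param x Channels x samples matrix with at least 2 channels.
#' @return Re-referenced matrix; cross-channel sums are 0 at every sample.
#' @export
car_reference <- function(x) {
  if (nrow(x) < 2)
    stop("car_reference: common average reference undefined for one channel")
  sweep(x, 2, colMeans(x))
}

#' Preprocess one epoch
#'
#' Applies notch, high-pass, and CAR (in that order, per [filter_spec()]) to a
#' full-montage epoch. CAR precedes channel selection, so epochs must carry
#' all recorded channels.
#'
#' @param epoch An [epoch()].
#' @param spec A [filter_spec()].
#' @return The filtered epoch with identical dimensions.
#' @export
preprocess_epoch <- function(epoch, spec = filter_spec()) {
  preprocess_epochs(list(epoch), spec)[[1]]
}

#' Preprocess a list of epochs sharing one sampling rate
#'
#' @param epochs List of [epoch()] objects.
#' @param spec A [filter_spec()].
#' @return List of filtered epochs.
#' @export
preprocess_epochs <- function(epochs, spec = filter_spec()) {
  if (length(epochs) == 0) return(epochs)
  fs <- epochs[[1]]$sampling_rate
  d <- .design_filters(spec, fs)
  lapply(epochs, function(ep) {
    x <- ep$samples
    if (spec$car && nrow(x) < 2)
      stop("preprocess_epoch: CAR requires more than one channel")
    x <- .filtfilt_mat(d$notch$b, d$notch$a, d$notch$zi, x, d$notch$npad)
    x <- .filtfilt_mat(d$hp$b, d$hp$a, d$hp$zi, x, d$hp$npad)
    if (spec$car) x <- car_reference(x)
    ep$samples <- x
    ep
  })
}
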