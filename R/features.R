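#' Spectral estimates for one epoch
#'
#' Computes, per channel, the one-sided periodogram of the epoch at its native
#' resolution (1 Hz for the default 1 s epochs), both as power spectral
#' density (uV^2/Hz) and as amplitude spectrum (uV), plus a finer PSD on a
#' half-native grid (0.5 Hz at defaults) obtained by zero-padding the epoch to
#' twice its length.
#'
#' @param ep An [epoch()] (or a channels x samples matrix via `fs`).
#' @param fs Sampling rate, required when `ep` is a bare matrix.
#' @return List with `freq1`, `psd1`, `amp1` (native grid) and `freq05`,
#'   `psd05` (half-native grid); spectra are channels x bins matrices.
#' @export
epoch_spectra <- function(ep, fs = NULL) {
  if (inherits(ep, "eeg_epoch")) {
    X <- ep$samples
    fs <- ep$sampling_rate
  } else {
    X <- as.matrix(ep)
    if (is.null(fs)) stop("epoch_spectra: fs required for a bare matrix")
  }
  N <- ncol(X)
  s1 <- .one_sided(stats::mvfft(t(X)), N, fs, N)
  X2 <- cbind(X, matrix(0, nrow(X), N))
  s2 <- .one_sided(stats::mvfft(t(X2)), 2L * N, fs, N)
  list(freq1 = s1$freq, psd1 = s1$psd, amp1 = s1$amp,
       freq05 = s2$freq, psd05 = s2$psd)
}

# One-sided periodogram from an FFT matrix (bins x channels). `neff` is the
# number of data samples (excludes zero padding) used for PSD scaling.
.one_sided <- function(ft, N, fs, neff) {
  half <- N %/% 2L
  idx <- seq_len(half + 1L)
  m <- Mod(ft[idx, , drop = FALSE])
  mult <- rep(2, half + 1L)
  mult[1] <- 1
  if (N %% 2L == 0L) mult[half + 1L] <- 1
  psd <- t(m^2 * mult / (fs * neff))
  amp <- t(m * mult / neff)
  list(freq = (idx - 1) * fs / N, psd = psd, amp = amp)
}

.band_idx <- function(freq, lo, hi, lo_open = FALSE) {
  eps <- 1e-9
  lo_ok <- if (lo_open) freq > lo + eps else freq >= lo - eps
  which(lo_ok & freq <= hi + eps)
}

#' Fit per-channel optimal frequencies (algorithm D training step)
#'
#' For each channel: the PSD of every epoch is evaluated on the 8-28 Hz band
#' at 0.5 Hz resolution, averaged within each class, and each class-mean
#' spectrum is normalised to unit sum over the band. The optimal frequency is
#' the grid point maximising the absolute difference between the normalised
#' start and rest spectra; ties resolve to the lowest frequency.
#'
#' @param rest_epochs,start_epochs Non-empty lists of epochs sharing the same
#'   channels.
#' @return Named numeric vector of class `optimal_frequencies`: one frequency
#'   in \[8, 28\] per channel.
#' @export
fit_optimal_frequencies <- function(rest_epochs, start_epochs) {
  if (length(rest_epochs) == 0 || length(start_epochs) == 0)
    stop("fit_optimal_frequencies: both classes must be non-empty")
  ch <- rest_epochs[[1]]$channel_names
  if (!identical(ch, start_epochs[[1]]$channel_names))
    stop("fit_optimal_frequencies: mismatched channel sets")
  mean_band_psd <- function(eps_list) {
    acc <- NULL
    freq <- NULL
    for (ep in eps_list) {
      sp <- epoch_spectra(ep)
      band <- .band_idx(sp$freq05, 8, 28)
      p <- sp$psd05[, band, drop = FALSE]
      if (is.null(acc)) {
        acc <- p
        freq <- sp$freq05[band]
      } else acc <- acc + p
    }
    list(psd = acc / length(eps_list), freq = freq)
  }
  rest <- mean_band_psd(rest_epochs)
  start <- mean_band_psd(start_epochs)
  .optf_core(rest$psd, start$psd, rest$freq, ch)
}

# Core of the optimal-frequency rule, shared with the batched evaluation
# path: class-mean band PSDs in, per-channel argmax frequency out.
.optf_core <- function(rest_mean, start_mean, freq, channels) {
  norm_rows <- function(m) {
    s <- rowSums(m)
    s[s == 0] <- 1
    m / s
  }
  d <- abs(norm_rows(start_mean) - norm_rows(rest_mean))
  f <- freq[apply(d, 1, which.max)]  # which.max: first (lowest) on ties
  names(f) <- channels
  structure(f, class = "optimal_frequencies")
}

.ALGORITHMS <- c("A", "B", "C", "D", "E")

#' Number of features per electrode for an algorithm
#' @param algorithm One of `"A"`..`"E"`.
#' @return 1 (A, B, D) or 3 (C, E).
#' @export
features_per_channel <- function(algorithm) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  if (algorithm %in% c("C", "E")) 3L else 1L
}

# Feature math shared by the single-epoch API and the batched evaluation
# path. `sp` is the output of epoch_spectra().
.features_from_spectra <- function(sp, algorithm, optf = NULL, channels = NULL) {
  switch(
    algorithm,
    A = rowMeans(sp$psd1[, .band_idx(sp$freq1, 18, 28), drop = FALSE]),
    B = sqrt(rowSums(sp$amp1[, .band_idx(sp$freq1, 0, 50), drop = FALSE]^2)),
    C = {
      m <- cbind(
        rowMeans(sp$psd1[, .band_idx(sp$freq1, 1, 4), drop = FALSE]),
        rowMeans(sp$psd1[, .band_idx(sp$freq1, 8, 12), drop = FALSE]),
        rowMeans(sp$psd1[, .band_idx(sp$freq1, 13, 28), drop = FALSE]))
      as.numeric(t(m))  # channel-major: 3 band means per channel
    },
    D = {
      f <- as.numeric(optf[channels])
      vapply(seq_along(f), function(i) {
        mean(sp$psd05[i, .band_idx(sp$freq05, f[i] - 1, f[i] + 1)])
      }, numeric(1))
    },
    E = {
      m <- cbind(
        rowSums(sp$amp1[, .band_idx(sp$freq1, 8, 12), drop = FALSE]),
        rowSums(sp$amp1[, .band_idx(sp$freq1, 12, 24, lo_open = TRUE),
                        drop = FALSE]),
        rowSums(sp$amp1[, .band_idx(sp$freq1, 24, 30, lo_open = TRUE),
                        drop = FALSE]))
      as.numeric(t(m))
    }
  )
}

#' Extract a feature vector from a preprocessed, channel-selected epoch
#'
#' The five spectral feature algorithms, each applied per electrode:
#' * **A** - mean band power (PSD) over 18-28 Hz; 1 feature/electrode.
#' * **B** - Euclidean norm of the 0-50 Hz amplitude spectrum at 1 Hz
#'   resolution; 1 feature/electrode.
#' * **C** - mean PSD of the 1-4, 8-12 and 13-28 Hz bands; 3
#'   features/electrode.
#' * **D** - mean PSD within +/-1 Hz of the electrode's optimal frequency
#'   (see [fit_optimal_frequencies()]); 1 feature/electrode.
#' * **E** - summed 1 Hz-resolution amplitude spectrum over mu (8-12 Hz),
#'   low beta (12-24 Hz\] and high beta (24-30 Hz\]; 3 features/electrode.
#'
#' @param ep An [epoch()].
#' @param algorithm One of `"A"`..`"E"`.
#' @param optimal_frequencies Required for algorithm D.
#' @return Named numeric feature vector (channel-major), with attributes
#'   `algorithm` and `epoch_start`.
#' @export
extract_features <- function(ep, algorithm,
                             optimal_frequencies = NULL) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  if (algorithm == "D") {
    if (is.null(optimal_frequencies))
      stop("extract_features: algorithm D requires optimal frequencies")
    missing <- setdiff(ep$channel_names, names(optimal_frequencies))
    if (length(missing))
      stop("extract_features: no optimal frequency for ",
           paste(missing, collapse = ", "))
  }
  sp <- epoch_spectra(ep)
  v <- .features_from_spectra(sp, algorithm, optimal_frequencies,
                              ep$channel_names)
  k <- features_per_channel(algorithm)
  names(v) <- if (k == 1) ep$channel_names else
    paste(rep(ep$channel_names, each = k), rep(seq_len(k),
                                               length(ep$channel_names)),
          sep = ".")
  attr(v, "algorithm") <- algorithm
  attr(v, "epoch_start") <- ep$start_time
  v
}
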