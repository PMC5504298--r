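#' Train the epoch classifier
#'
#' Standardises the training features (z-score with training-set statistics)
#' and fits an RBF-kernel support-vector machine with cost 1 and
#' `gamma = 1 / (n_features x variance of the standardised feature matrix)`.
#' Hyperparameters and scaler statistics are stored in the model for
#' reproducibility.
#'
#' @param features Numeric matrix, examples x features.
#' @param labels Vector of class labels: 0/"rest" vs 1/"start"; both classes
#'   must be present.
#' @param algorithm,config,optimal_frequencies,window_type Optional provenance
#'   stored with the model.
#' @param cost SVM cost parameter.
#' @return An object of class `pedal_model`.
#' @export
train_model <- function(features, labels, algorithm = NULL, config = NULL,
                        optimal_frequencies = NULL, window_type = NULL,
                        cost = 1) {
  x <- as.matrix(features)
  y <- .labels01(labels)
  if (nrow(x) != length(y))
    stop("train_model: ", nrow(x), " feature rows but ", length(y), " labels")
  if (length(unique(y)) < 2)
    stop("train_model: both classes must be present")
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  v <- stats::var(as.numeric(xs))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(xs) * v) else 1 / ncol(xs)
  fit <- e1071::svm(xs, factor(y, levels = c(0, 1)), kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scl, gamma = gamma,
                 cost = cost, algorithm = algorithm, config = config,
                 optimal_frequencies = optimal_frequencies,
                 window_type = window_type),
            class = "pedal_model")
}

.labels01 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    bad <- setdiff(unique(l), c("rest", "start"))
    if (length(bad)) stop("labels must be rest/start or 0/1")
    as.integer(l == "start")
  } else as.integer(labels)
}

#' Predict epoch classes (0 = nothing, 1 = detection)
#'
#' @param object A [train_model()] fit.
#' @param newdata Feature matrix with the training feature count.
#' @param ... Unused.
#' @return Integer vector of 0/1 epoch predictions.
#' @export
predict.pedal_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$center))
    stop("predict: feature count mismatch")
  xs <- scale(x, center = object$center, scale = object$scale)
  as.integer(as.character(predict(object$fit, xs)))
}

#' Majority vote over the epoch predictions of one class window
#'
#' Returns 1 iff strictly more than half of the predictions are 1; ties
#' resolve to 0 (no detection).
#'
#' @param predictions Non-empty 0/1 vector.
#' @return 0 or 1.
#' @export
majority_vote <- function(predictions) {
  if (length(predictions) == 0) stop("majority_vote: empty prediction list")
  as.integer(sum(predictions == 1) > length(predictions) / 2)
}

#' Voting-queue detections over a causal prediction stream
#'
#' A pedaling-initiation detection fires when `consecutive` successive epoch
#' predictions are 1, timestamped at the end of the last epoch of the run.
#' After firing, the queue disarms until a negative prediction rearms it, so
#' one sustained activation yields exactly one detection.
#'
#' @param predictions 0/1 vector in temporal order.
#' @param epoch_end_times Epoch end times, seconds, same length.
#' @param consecutive Run length required (default 5).
#' @return Numeric vector of detection times (possibly empty), strictly
#'   increasing.
#' @export
voting_queue_detections <- function(predictions, epoch_end_times,
                                    consecutive = 5) {
  if (length(predictions) != length(epoch_end_times))
    stop("voting_queue_detections: length mismatch")
  run <- 0L
  armed <- TRUE
  out <- numeric(0)
  for (i in seq_along(predictions)) {
    if (predictions[i] == 1) {
      if (armed) {
        run <- run + 1L
        if (run == consecutive) {
          out <- c(out, epoch_end_times[i])
          run <- 0L
          armed <- FALSE
        }
      }
    } else {
      run <- 0L
      armed <- TRUE
    }
  }
  out
}

# ---- batched epoch caches ---------------------------------------------------
# Preprocessing (notch + high-pass + CAR on the full montage) and spectral
# estimation are montage-independent, so they are computed once per session
# and shared across the (algorithm x configuration) grid.

.trim_spectra <- function(sp, keep1, keep05) {
  list(freq1 = sp$freq1[keep1], psd1 = sp$psd1[, keep1, drop = FALSE],
       amp1 = sp$amp1[, keep1, drop = FALSE], freq05 = sp$freq05[keep05],
       psd05 = sp$psd05[, keep05, drop = FALSE])
}

# Preprocess raw epochs and compute trimmed spectra for `channels` only.
# Exploits that the common average reference (a fixed channel-mixing matrix)
# commutes exactly with the identical per-channel zero-phase filters, so CAR
# is applied first on the full montage and the IIR filtering is then
# restricted to the channels the evaluation grid needs; the result is
# numerically identical to the notch -> high-pass -> CAR order of
# [preprocess_epoch()].
.preprocess_spectra <- function(epochs, fspec, channels) {
  if (length(epochs) == 0) return(list())
  ci <- match(channels, epochs[[1]]$channel_names)
  if (anyNA(ci))
    stop("cache: epoch missing channel(s) ",
         paste(channels[is.na(ci)], collapse = ", "))
  fs <- epochs[[1]]$sampling_rate
  d <- .design_filters(fspec, fs)
  keep1 <- keep05 <- NULL
  lapply(epochs, function(ep) {
    x <- ep$samples
    if (fspec$car) {
      if (nrow(x) < 2)
        stop("preprocess_epoch: CAR requires more than one channel")
      x <- car_reference(x)
    }
    x <- x[ci, , drop = FALSE]
    x <- .filtfilt_mat(d$notch$b, d$notch$a, d$notch$zi, x, d$notch$npad)
    x <- .filtfilt_mat(d$hp$b, d$hp$a, d$hp$zi, x, d$hp$npad)
    sp <- epoch_spectra(x, fs)
    if (is.null(keep1)) {
      keep1 <<- .band_idx(sp$freq1, 0, 50)
      keep05 <<- .band_idx(sp$freq05, 0, 31)
    }
    .trim_spectra(sp, keep1, keep05)
  })
}

# Labeled class-window epochs (preprocessed, spectra cached) for the
# non-discarded cycles of `trials` (default: all).
.class_epoch_cache <- function(session, window_type, epoch_length = 1,
                               shift = 0.2, fspec = filter_spec(), channels,
                               trials = NULL) {
  ev <- session$events
  ev <- ev[!ev$discarded & !is.na(ev$real_start_time_s), ]
  if (!is.null(trials)) ev <- ev[ev$trial %in% trials, ]
  if (nrow(ev) == 0) stop("no usable (non-discarded, onset-bearing) cycles")
  epochs <- list()
  rows <- vector("list", 2L * nrow(ev))
  k <- 0L
  for (i in seq_len(nrow(ev))) {
    w <- build_class_windows(ev$real_start_time_s[i], window_type,
                             ev$cycle_start_s[i])
    for (lbl in c("rest", "start")) {
      wi <- w[[lbl]]
      eps <- slice_epochs(session$eeg, c(wi$t0, wi$t1), epoch_length, shift)
      k <- k + 1L
      rows[[k]] <- data.frame(
        trial = ev$trial[i], cycle = ev$cycle[i], label = lbl,
        win = paste(ev$trial[i], ev$cycle[i], lbl, sep = "/"),
        n = length(eps))
      epochs <- c(epochs, eps)
    }
  }
  index_w <- do.call(rbind, rows[seq_len(k)])
  index <- index_w[rep(seq_len(nrow(index_w)), index_w$n),
                   c("trial", "cycle", "label", "win")]
  rownames(index) <- NULL
  list(index = index, spectra = .preprocess_spectra(epochs, fspec, channels),
       channels = channels)
}

# Continuous per-cycle epoch stream (preprocessed, spectra cached) for the
# pseudo-online test pass over `trials`.
.stream_epoch_cache <- function(session, trials, epoch_length = 1,
                                shift = 0.2, fspec = filter_spec(), channels) {
  ev <- session$events
  ev <- ev[ev$trial %in% trials & !ev$discarded &
             !is.na(ev$real_start_time_s), ]
  if (nrow(ev) == 0) stop("no usable test cycles")
  epochs <- list()
  rows <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    eps <- slice_epochs(session$eeg, c(ev$cycle_start_s[i], ev$cycle_end_s[i]),
                        epoch_length, shift)
    rows[[i]] <- data.frame(
      trial = ev$trial[i], cycle = ev$cycle[i],
      onset = ev$real_start_time_s[i], cycle_start = ev$cycle_start_s[i],
      cycle_end = ev$cycle_end_s[i],
      start_time = vapply(eps, function(e) e$start_time, numeric(1)))
    epochs <- c(epochs, eps)
  }
  index <- do.call(rbind, rows)
  rownames(index) <- NULL
  list(index = index, spectra = .preprocess_spectra(epochs, fspec, channels),
       channels = channels)
}

# Feature matrix (rows = epochs) for one algorithm/configuration from a
# spectra cache; `rows` restricts to a subset of epochs.
.features_matrix <- function(cache, algorithm, config_channels, optf = NULL,
                             rows = NULL) {
  ci <- match(config_channels, cache$channels)
  if (anyNA(ci))
    stop("cache does not cover channel(s) ",
         paste(config_channels[is.na(ci)], collapse = ", "))
  if (is.null(rows)) rows <- seq_along(cache$spectra)
  nf <- length(config_channels) * features_per_channel(algorithm)
  out <- matrix(0, nrow = length(rows), ncol = nf)
  for (r in seq_along(rows)) {
    sp <- cache$spectra[[rows[r]]]
    sub <- list(freq1 = sp$freq1, psd1 = sp$psd1[ci, , drop = FALSE],
                amp1 = sp$amp1[ci, , drop = FALSE], freq05 = sp$freq05,
                psd05 = sp$psd05[ci, , drop = FALSE])
    out[r, ] <- .features_from_spectra(sub, algorithm, optf, config_channels)
  }
  out
}

.fit_optf_from_cache <- function(cache, rest_rows, start_rows,
                                 config_channels) {
  ci <- match(config_channels, cache$channels)
  freq <- cache$spectra[[1]]$freq05
  band <- .band_idx(freq, 8, 28)
  mean_psd <- function(rr) {
    acc <- 0
    for (r in rr) acc <- acc + cache$spectra[[r]]$psd05[ci, band, drop = FALSE]
    acc / length(rr)
  }
  .optf_core(mean_psd(rest_rows), mean_psd(start_rows), freq[band],
             config_channels)
}

# Offline cross-validation core on precomputed features: leave-one-trial-out,
# per-window majority vote, per-fold count metrics averaged across folds.
.offline_cv_core <- function(feat, labels01, trial_ids, win_ids, window_type,
                             refit = NULL) {
  trials <- sort(unique(trial_ids))
  if (length(trials) < 2) stop("offline evaluation needs at least 2 trials")
  per <- vector("list", length(trials))
  for (f in seq_along(trials)) {
    te <- trial_ids == trials[f]
    tr <- !te
    if (is.null(refit)) {
      ftr <- feat[tr, , drop = FALSE]
      fte <- feat[te, , drop = FALSE]
    } else {
      fl <- refit(which(tr), which(te))
      ftr <- fl$train
      fte <- fl$test
    }
    model <- train_model(ftr, labels01[tr])
    pred <- predict(model, fte)
    wins <- win_ids[te]
    lab <- labels01[te]
    uw <- unique(wins)
    vote <- vapply(uw, function(w) majority_vote(pred[wins == w]), integer(1))
    truth <- vapply(uw, function(w) lab[wins == w][1], integer(1))
    n_events <- sum(truth == 1)
    true_det <- sum(truth == 1 & vote == 1)
    false_det <- sum(truth == 0 & vote == 1)
    rest_min <- sum(truth == 0) * window_length_s(window_type) / 60
    m <- compute_counts_metrics(true_det, n_events, false_det, rest_min)
    per[[f]] <- data.frame(trial = trials[f], tpr = m$tpr,
                           fp_per_min = m$fp_per_min, acc = m$acc,
                           n_events = n_events, true_det = true_det,
                           false_det = false_det)
  }
  do.call(rbind, per)
}

#' Offline evaluation: leave-one-trial-out cross-validation
#'
#' For each fold, one trial is held out and the classifier is trained on the
#' labeled class-window epochs of the remaining trials (for algorithm D the
#' optimal frequencies are refit within each fold). Held-out epoch
#' predictions are grouped per class window (16 per group for 4 s windows, 6
#' for 2 s) and reduced by majority vote; a start window voted 1 is a true
#' detection, a rest window voted 1 a false detection. Count metrics are
#' computed per fold and averaged across folds; offline rest time is the
#' summed duration of the rest-window decisions.
#'
#' @param session A [bci_session()] with detected onsets.
#' @param algorithm Feature algorithm `"A"`..`"E"`.
#' @param config Electrode configuration (id or object).
#' @param window_type `"4s"` or `"2s"`.
#' @param epoch_length,shift Epoching parameters, seconds.
#' @param fspec A [filter_spec()].
#' @param configs Configuration table used when `config` is an id.
#' @param cache Internal: a precomputed class-epoch cache.
#' @return An [evaluation_result()] with per-fold data in `per_split`.
#' @export
evaluate_offline <- function(session, algorithm, config, window_type = "4s",
                             epoch_length = 1, shift = 0.2,
                             fspec = filter_spec(),
                             configs = electrode_configurations(),
                             cache = NULL) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  if (!is.list(config)) config <- get_configuration(config, configs)
  if (is.null(cache))
    cache <- .class_epoch_cache(session, window_type, epoch_length, shift,
                                fspec, config$channels)
  idx <- cache$index
  labels01 <- as.integer(idx$label == "start")
  refit <- NULL
  feat <- NULL
  if (algorithm == "D") {
    refit <- function(tr_rows, te_rows) {
      optf <- .fit_optf_from_cache(cache, tr_rows[labels01[tr_rows] == 0],
                                   tr_rows[labels01[tr_rows] == 1],
                                   config$channels)
      list(train = .features_matrix(cache, "D", config$channels, optf,
                                    tr_rows),
           test = .features_matrix(cache, "D", config$channels, optf,
                                   te_rows))
    }
  } else {
    feat <- .features_matrix(cache, algorithm, config$channels)
  }
  per <- .offline_cv_core(feat, labels01, idx$trial, idx$win, window_type,
                          refit)
  w <- wd_weights("offline", window_type)
  per$wd <- mapply(function(tpr, acc, fp) compute_wd(tpr, acc, fp, w),
                   per$tpr, per$acc, per$fp_per_min)
  evaluation_result(mean(per$tpr), mean(per$fp_per_min), mean(per$acc), w,
                    counts = list(n_true_events = sum(per$n_events),
                                  n_true_detections = sum(per$true_det),
                                  n_false_detections = sum(per$false_det)),
                    per_split = per)
}

#' Pseudo-online evaluation: causal sliding-window voting queue
#'
#' The model is trained on the labeled class-window epochs of the training
#' trials only (first 10 of 16 by default). Every 200 ms-stepped epoch of
#' each test cycle is then classified in temporal order and passed through
#' the voting queue ([voting_queue_detections()]); a detection whose
#' timestamp lies inside the cycle's start class window is a true detection
#' (counted at most once per window), otherwise a false positive. Count
#' metrics are computed per test trial and averaged; rest time per trial is
#' the summed cycle duration minus the start class windows.
#'
#' @inheritParams evaluate_offline
#' @param train_trials Trials used for training (default: all but the last
#'   6).
#' @param consecutive Voting-queue run length (default 5; with the 200 ms
#'   shift, one detection spans 1 s).
#' @param train_cache,test_cache Internal: precomputed caches.
#' @return List with `detections` (data.frame: time, trial, cycle, is_true)
#'   and `result` (an [evaluation_result()] with per-trial data, including
#'   per-trial WD, in `per_split`).
#' @export
evaluate_pseudo_online <- function(session, algorithm, config,
                                   window_type = "4s", train_trials = NULL,
                                   epoch_length = 1, shift = 0.2,
                                   fspec = filter_spec(),
                                   configs = electrode_configurations(),
                                   consecutive = 5, train_cache = NULL,
                                   test_cache = NULL) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  if (!is.list(config)) config <- get_configuration(config, configs)
  all_trials <- sort(unique(session$events$trial))
  if (is.null(train_trials))
    train_trials <- utils::head(all_trials, max(1, length(all_trials) - 6))
  test_trials <- setdiff(all_trials, train_trials)
  if (length(test_trials) == 0)
    stop("evaluate_pseudo_online: no test trials left")
  if (is.null(train_cache))
    train_cache <- .class_epoch_cache(session, window_type, epoch_length,
                                      shift, fspec, config$channels,
                                      trials = train_trials)
  if (is.null(test_cache))
    test_cache <- .stream_epoch_cache(session, test_trials, epoch_length,
                                      shift, fspec, config$channels)
  idx <- train_cache$index
  labels01 <- as.integer(idx$label == "start")
  optf <- NULL
  if (algorithm == "D")
    optf <- .fit_optf_from_cache(train_cache, which(labels01 == 0),
                                 which(labels01 == 1), config$channels)
  model <- train_model(.features_matrix(train_cache, algorithm,
                                        config$channels, optf),
                       labels01, algorithm = algorithm, config = config,
                       optimal_frequencies = optf, window_type = window_type)
  pred <- predict(model, .features_matrix(test_cache, algorithm,
                                          config$channels, optf))

  tidx <- test_cache$index
  det <- list()
  agg <- list()
  for (tt in test_trials) {
    n_events <- 0L
    true_det <- 0L
    false_det <- 0L
    rest_s <- 0
    cyc <- unique(tidx[tidx$trial == tt, c("cycle", "onset", "cycle_start",
                                           "cycle_end")])
    for (j in seq_len(nrow(cyc))) {
      rows <- which(tidx$trial == tt & tidx$cycle == cyc$cycle[j])
      ends <- tidx$start_time[rows] + epoch_length
      times <- voting_queue_detections(pred[rows], ends, consecutive)
      w <- build_class_windows(cyc$onset[j], window_type)
      is_true <- times >= w$start$t0 & times < w$start$t1
      n_events <- n_events + 1L
      true_det <- true_det + as.integer(any(is_true))
      false_det <- false_det + sum(!is_true)
      rest_s <- rest_s + (cyc$cycle_end[j] - cyc$cycle_start[j]) -
        window_length_s(window_type)
      if (length(times))
        det[[length(det) + 1]] <- data.frame(time = times, trial = tt,
                                             cycle = cyc$cycle[j],
                                             is_true = is_true)
    }
    m <- compute_counts_metrics(true_det, n_events, false_det, rest_s / 60)
    agg[[length(agg) + 1]] <- data.frame(
      trial = tt, tpr = m$tpr, fp_per_min = m$fp_per_min, acc = m$acc,
      n_events = n_events, true_det = true_det, false_det = false_det)
  }
  per <- do.call(rbind, agg)
  w <- wd_weights("pseudo-online")
  per$wd <- mapply(function(tpr, acc, fp) compute_wd(tpr, acc, fp, w),
                   per$tpr, per$acc, per$fp_per_min)
  res <- evaluation_result(mean(per$tpr), mean(per$fp_per_min), mean(per$acc),
                           w,
                           counts = list(
                             n_true_events = sum(per$n_events),
                             n_true_detections = sum(per$true_det),
                             n_false_detections = sum(per$false_det)),
                           per_split = per)
  detections <- if (length(det)) do.call(rbind, det) else
    data.frame(time = numeric(0), trial = integer(0), cycle = integer(0),
               is_true = logical(0))
  list(detections = detections, result = res, model = model)
}

#' Evaluate a grid of algorithms and electrode configurations
#'
#' Runs [evaluate_offline()] or [evaluate_pseudo_online()] for every
#' (configuration, algorithm) cell, sharing one preprocessing and spectral
#' cache across the grid, and collects WD values into a configuration x
#' algorithm matrix.
#'
#' @inheritParams evaluate_pseudo_online
#' @param algorithms Algorithms to evaluate (default all five).
#' @param config_ids Configuration ids to evaluate (default 1:8).
#' @param mode `"offline"` or `"pseudo-online"`.
#' @return A `wd_matrix`: numeric matrix (rows = configurations, columns =
#'   algorithms) with attributes `subject`, `mode`, `window_type` and, for
#'   pseudo-online runs, `per_trial` (per-cell per-trial WD data).
#' @export
evaluate_grid <- function(session, algorithms = .ALGORITHMS,
                          config_ids = 1:8,
                          mode = c("offline", "pseudo-online"),
                          window_type = "4s", train_trials = NULL,
                          epoch_length = 1, shift = 0.2,
                          fspec = filter_spec(),
                          configs = electrode_configurations(),
                          consecutive = 5) {
  mode <- match.arg(mode)
  cfg <- lapply(config_ids, get_configuration, configs = configs)
  channels <- unique(unlist(lapply(cfg, `[[`, "channels")))
  m <- matrix(NA_real_, nrow = length(cfg), ncol = length(algorithms),
              dimnames = list(as.character(config_ids), algorithms))
  per_trial <- list()
  if (mode == "offline") {
    cache <- .class_epoch_cache(session, window_type, epoch_length, shift,
                                fspec, channels)
    for (i in seq_along(cfg)) for (a in algorithms)
      m[i, a] <- evaluate_offline(session, a, cfg[[i]], window_type,
                                  epoch_length, shift, fspec,
                                  cache = cache)$wd
  } else {
    all_trials <- sort(unique(session$events$trial))
    if (is.null(train_trials))
      train_trials <- utils::head(all_trials, max(1, length(all_trials) - 6))
    train_cache <- .class_epoch_cache(session, window_type, epoch_length,
                                      shift, fspec, channels,
                                      trials = train_trials)
    test_cache <- .stream_epoch_cache(session,
                                      setdiff(all_trials, train_trials),
                                      epoch_length, shift, fspec, channels)
    for (i in seq_along(cfg)) for (a in algorithms) {
      r <- evaluate_pseudo_online(session, a, cfg[[i]], window_type,
                                  train_trials, epoch_length, shift, fspec,
                                  consecutive = consecutive,
                                  train_cache = train_cache,
                                  test_cache = test_cache)
      m[i, a] <- r$result$wd
      per_trial[[paste(config_ids[i], a, sep = "/")]] <- r$result$per_split
    }
  }
  wd_matrix(m, subject = session$subject_id, mode = mode,
            window_type = window_type, per_trial = per_trial)
}
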