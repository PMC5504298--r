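#' WD matrix
#'
#' Per-subject grid of weighted-discriminator values over electrode
#' configurations (rows) and feature algorithms (columns) for one analysis
#' mode and window type.
#'
#' @param m Numeric matrix with configuration ids as rownames and algorithm
#'   ids as colnames.
#' @param subject,mode,window_type Provenance attributes.
#' @param per_trial Optional list of per-trial WD data per cell.
#' @return Object of class `wd_matrix`.
#' @export
wd_matrix <- function(m, subject = NA_character_,
                      mode = c("offline", "pseudo-online"),
                      window_type = "4s", per_trial = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("wd_matrix: needs configuration rownames and algorithm colnames")
  structure(m, class = c("wd_matrix", "matrix", "array"), subject = subject,
            mode = match.arg(mode), window_type = window_type,
            per_trial = per_trial)
}

#' @export
print.wd_matrix <- function(x, ...) {
  cat(sprintf("<wd_matrix> subject %s, %s, %s windows\n", attr(x, "subject"),
              attr(x, "mode"), attr(x, "window_type")))
  print(round(matrix(as.numeric(x), nrow(x), dimnames = dimnames(x)), 2))
  invisible(x)
}

#' Electrode-configuration-averaged WD per algorithm
#'
#' Arithmetic mean of each algorithm's column over the electrode
#' configurations.
#'
#' @param m A [wd_matrix()] (or plain matrix with algorithm columns).
#' @return Named numeric vector, one mean WD per algorithm.
#' @export
ec_averaged_wd <- function(m) {
  if (any(!is.finite(m))) stop("ec_averaged_wd: incomplete WD grid")
  colMeans(unclass(m)[, , drop = FALSE])
}

#' Personalized model selection
#'
#' The three-step per-subject procedure:
#' 1. keep the two algorithms with the highest configuration-averaged WD;
#' 2. among their cells, preselect the maximum WD and every cell within
#'    `tol` of it;
#' 3. choose the preselected cell with the fewest electrodes; break ties by
#'    the higher WD, and remaining ties uniformly at random.
#'
#' When the matrix holds exactly two algorithm columns (a pre-restricted
#' grid), step 1 keeps both.
#'
#' @param m A [wd_matrix()].
#' @param sizes Named electrode counts per configuration id
#'   ([config_sizes()]).
#' @param tol Preselection tolerance below the maximum WD (default 0.01).
#' @param tie_seed Optional integer seed consumed only by the final random
#'   tie-break (recorded in the audit trail).
#' @return A list of class `selection_result`: `algorithm`, `config_id`,
#'   `wd`, plus audit fields `best_two`, `preselected` (data.frame) and
#'   `random_tie`.
#' @export
select_personalized <- function(m, sizes = config_sizes(), tol = 0.01,
                                tie_seed = NULL) {
  if (any(!is.finite(m))) stop("select_personalized: incomplete WD grid")
  missing_sizes <- setdiff(rownames(m), names(sizes))
  if (length(missing_sizes))
    stop("select_personalized: no electrode count for configuration(s) ",
         paste(missing_sizes, collapse = ", "))
  avg <- ec_averaged_wd(m)
  best_two <- names(sort(avg, decreasing = TRUE))[seq_len(min(2, length(avg)))]
  cells <- unclass(m)[, best_two, drop = FALSE]
  eps <- 1e-12
  mx <- max(cells)
  hit <- which(cells >= mx - tol - eps, arr.ind = TRUE)
  pre <- data.frame(config_id = rownames(cells)[hit[, 1]],
                    algorithm = best_two[hit[, 2]],
                    wd = cells[hit], size = sizes[rownames(cells)[hit[, 1]]],
                    stringsAsFactors = FALSE)
  pre <- pre[order(pre$size, -pre$wd), ]
  cand <- pre[pre$size == pre$size[1], ]
  cand <- cand[cand$wd >= cand$wd[1] - eps, ]
  random_tie <- nrow(cand) > 1
  pick <- if (random_tie) {
    if (!is.null(tie_seed)) .with_seed(tie_seed, sample.int(nrow(cand), 1))
    else sample.int(nrow(cand), 1)
  } else 1L
  structure(list(algorithm = cand$algorithm[pick],
                 config_id = cand$config_id[pick], wd = cand$wd[pick],
                 best_two = best_two, preselected = pre,
                 random_tie = random_tie,
                 subject = attr(m, "subject"), mode = attr(m, "mode"),
                 window_type = attr(m, "window_type")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> algorithm %s, configuration %s (WD %.2f)%s\n",
              x$algorithm, x$config_id, x$wd,
              if (x$random_tie) " [random tie-break]" else ""))
  invisible(x)
}

#' Best uniform (subject-independent) algorithm
#'
#' Averages each algorithm's configuration-averaged WD across subjects and
#' returns the algorithm with the highest grand mean; exact ties resolve to
#' the first algorithm column.
#'
#' @param matrices List of per-subject [wd_matrix()] objects sharing the
#'   same algorithm columns.
#' @return Algorithm id (character).
#' @export
select_uniform_algorithm <- function(matrices) {
  avgs <- vapply(matrices, ec_averaged_wd,
                 numeric(ncol(matrices[[1]])))
  grand <- if (is.matrix(avgs)) rowMeans(avgs) else avgs
  names(grand)[which.max(grand)]
}

#' Best uniform electrode configuration for a fixed algorithm
#'
#' Averages the fixed algorithm's WD across subjects per configuration and
#' returns the configuration with the highest mean.
#'
#' @param matrices List of per-subject [wd_matrix()] objects.
#' @param algorithm The fixed algorithm id.
#' @return Configuration id (character).
#' @export
select_uniform_configuration <- function(matrices, algorithm) {
  cols <- vapply(matrices, function(m) unclass(m)[, algorithm],
                 numeric(nrow(matrices[[1]])))
  grand <- if (is.matrix(cols)) rowMeans(cols) else cols
  names(grand) <- rownames(matrices[[1]])
  names(grand)[which.max(grand)]
}

#' Configuration choice for one subject under a fixed algorithm
#'
#' The personalized-configuration step used when the algorithm is fixed
#' cohort-wide: preselect the maximum WD of the algorithm's column and all
#' values within `tol`, then apply the fewest-electrodes / highest-WD /
#' random tie-break.
#'
#' @inheritParams select_personalized
#' @param algorithm Fixed algorithm id.
#' @return A `selection_result`.
#' @export
select_configuration_for <- function(m, algorithm, sizes = config_sizes(),
                                     tol = 0.01, tie_seed = NULL) {
  select_personalized(wd_matrix(unclass(m)[, algorithm, drop = FALSE],
                                subject = attr(m, "subject"),
                                mode = if (is.null(attr(m, "mode"))) "offline"
                                       else attr(m, "mode"),
                                window_type = attr(m, "window_type")),
                      sizes = sizes, tol = tol, tie_seed = tie_seed)
}

#' Paired Wilcoxon signed-rank comparison of WD samples
#'
#' Two-sided signed-rank test on paired WD values (e.g. per subject x test
#' trial, personalized vs uniform model). Zero differences are dropped
#' (Wilcoxon convention); with no nonzero differences the samples are
#' indistinguishable and p = 1. For n <= 25 the exact null distribution of
#' the positive-rank sum is computed (a convolution over signed average
#' ranks, valid under ties); above that, the normal approximation with tie
#' correction is used.
#'
#' @param wd_a,wd_b Equal-length numeric vectors of paired WD values.
#' @return List `(statistic, p_value, n, method)` where `statistic` is the
#'   positive-rank sum V.
#' @export
compare_paired_wd <- function(wd_a, wd_b) {
  if (length(wd_a) != length(wd_b))
    stop("compare_paired_wd: length mismatch")
  d <- wd_a - wd_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, n = 0, method = "degenerate"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of 2*V by convolution (2r is always integer,
    # also for midranks)
    r2 <- as.integer(round(2 * r))
    probs <- 1
    for (ri in r2) {
      p_new <- numeric(length(probs) + ri)
      p_new[seq_along(probs)] <- probs * 0.5
      p_new[ri + seq_along(probs)] <- p_new[ri + seq_along(probs)] +
        probs * 0.5
      probs <- p_new
    }
    support <- seq_along(probs) - 1  # values of 2*V
    mu <- n * (n + 1) / 2            # mean of 2*V
    dev <- abs(2 * v - mu)
    p <- sum(probs[abs(support - mu) >= dev - 1e-9])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = min(1, p), n = n, method = method)
}
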