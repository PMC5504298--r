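.sin_epoch <- function(freqs, amps, nch = 1, fs = 500, n = 500,
                       phases = NULL) {
  t <- (seq_len(n) - 1) / fs
  x <- rep(0, n)
  if (is.null(phases)) phases <- rep(0, length(freqs))
  for (i in seq_along(freqs))
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
  epoch(matrix(x, nch, n, byrow = TRUE), paste0("e", seq_len(nch)), fs)
}

test_that("feature-vector lengths honour the per-electrode counts", {
  set.seed(9)
  ep <- epoch(matrix(rnorm(5 * 500), 5), paste0("e", 1:5), 500)
  optf <- structure(stats::setNames(rep(10, 5), paste0("e", 1:5)),
                    class = "optimal_frequencies")
  expect_length(extract_features(ep, "A"), 5)
  expect_length(extract_features(ep, "B"), 5)
  expect_length(extract_features(ep, "C"), 15)
  expect_length(extract_features(ep, "D", optf), 5)
  expect_length(extract_features(ep, "E"), 15)
  expect_error(extract_features(ep, "D"), "optimal frequencies")
  expect_error(extract_features(ep, "Z"))
})

test_that("algorithm A equals a brute-force periodogram band mean", {
  for (a in c(1, 7.5)) {
    ep <- .sin_epoch(20, a)
    got <- as.numeric(extract_features(ep, "A"))
    want <- oracle_band_psd(ep$samples[1, ], 500, 18, 28)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("zero input yields zero features for every algorithm", {
  ep <- epoch(matrix(0, 3, 500), paste0("e", 1:3), 500)
  optf <- structure(stats::setNames(rep(10, 3), paste0("e", 1:3)),
                    class = "optimal_frequencies")
  for (alg in c("A", "B", "C", "E"))
    expect_true(all(extract_features(ep, alg) == 0))
  expect_true(all(extract_features(ep, "D", optf) == 0))
})

test_that("features scale as PSD (a^2) or amplitude (a) under gain", {
  set.seed(10)
  x <- matrix(rnorm(2 * 500), 2)
  a <- 2.5
  ep1 <- epoch(x, c("e1", "e2"), 500)
  ep2 <- epoch(a * x, c("e1", "e2"), 500)
  optf <- structure(stats::setNames(c(10, 12), c("e1", "e2")),
                    class = "optimal_frequencies")
  for (alg in c("A", "C"))
    expect_equal(extract_features(ep2, alg),
                 a^2 * extract_features(ep1, alg), tolerance = 1e-9)
  expect_equal(extract_features(ep2, "D", optf),
               a^2 * extract_features(ep1, "D", optf), tolerance = 1e-9)
  for (alg in c("B", "E"))
    expect_equal(extract_features(ep2, alg),
                 a * extract_features(ep1, alg), tolerance = 1e-9)
  # nonnegativity
  for (alg in c("A", "B", "C", "E"))
    expect_true(all(extract_features(ep1, alg) >= 0))
})

test_that("the optimal frequency finds the attenuated band", {
  # rest: strong 10 Hz + bystanders at 15/20 Hz; start: only 10 Hz reduced
  rest <- lapply(1:4, function(i)
    .sin_epoch(c(10, 15, 20), c(4, 2, 2), nch = 2))
  start <- lapply(1:4, function(i)
    .sin_epoch(c(10, 15, 20), c(1, 2, 2), nch = 2))
  optf <- fit_optimal_frequencies(rest, start)
  expect_equal(unname(unclass(optf)), c(10, 10))
})

test_that("identical classes tie-break to the lowest grid frequency", {
  eps <- lapply(1:3, function(i) .sin_epoch(c(10, 20), c(3, 2), nch = 2))
  optf <- fit_optimal_frequencies(eps, eps)
  expect_equal(unname(unclass(optf)), c(8, 8))
})

test_that("the optimal-frequency grid is 8..28 Hz in 0.5 Hz steps", {
  sp <- epoch_spectra(epoch(matrix(0, 1, 500), "e1", 500))
  grid <- sp$freq05[sp$freq05 >= 8 - 1e-9 & sp$freq05 <= 28 + 1e-9]
  expect_equal(grid, seq(8, 28, by = 0.5))
  expect_length(grid, 41)
})

test_that("algorithm D's band mean matches an independent implementation", {
  set.seed(11)
  ep <- epoch(matrix(rnorm(2 * 500), 2), c("e1", "e2"), 500)
  optf <- structure(stats::setNames(c(10, 21.5), c("e1", "e2")),
                    class = "optimal_frequencies")
  got <- unname(extract_features(ep, "D", optf))
  # oracle: zero-padded periodogram band mean from the DFT definition
  oracle_padded <- function(x, fs, lo, hi) {
    n <- length(x)
    xp <- c(x, rep(0, n))
    p <- 2 * abs(fft(xp))^2 / (fs * n)
    f <- (seq_along(xp) - 1) * fs / (2 * n)
    keep <- f >= lo - 1e-9 & f <= hi + 1e-9
    mean(p[keep])
  }
  expect_equal(got[1], oracle_padded(ep$samples[1, ], 500, 9, 11),
               tolerance = 1e-9)
  expect_equal(got[2], oracle_padded(ep$samples[2, ], 500, 20.5, 22.5),
               tolerance = 1e-9)
})
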