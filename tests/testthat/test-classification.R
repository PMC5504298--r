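test_that("a separable problem is learned perfectly and deterministically", {
  set.seed(20)
  x <- rbind(matrix(rnorm(60, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(60, mean = 4, sd = 0.3), ncol = 2))
  y <- rep(c(0, 1), each = 30)
  m1 <- train_model(x, y)
  expect_identical(predict(m1, x), as.integer(y))
  probe <- matrix(rnorm(40), ncol = 2)
  m2 <- train_model(x, y)
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("training rejects malformed inputs", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(train_model(x, rep(0, 9)), "labels")
  expect_error(train_model(x, rep(1, 10)), "both classes")
  expect_error(predict(train_model(x, rep(c(0, 1), 5)),
                       matrix(0, 2, 3)), "mismatch")
})

test_that("majority vote needs a strict majority; ties are rest", {
  expect_identical(majority_vote(c(rep(1, 9), rep(0, 7))), 1L)
  expect_identical(majority_vote(c(rep(1, 8), rep(0, 8))), 0L)
  expect_identical(majority_vote(c(1, 1, 1, 0, 0, 0)), 0L)
  expect_identical(majority_vote(c(1, 1, 1, 1, 0, 0)), 1L)
  expect_error(majority_vote(integer(0)), "empty")
})

test_that("the voting queue fires on 5 consecutive positives and rearms", {
  ends <- seq(1, by = 0.2, length.out = 10)
  expect_equal(voting_queue_detections(c(0, 1, 1, 1, 1, 1, 0), ends[1:7]),
               ends[6])
  # a sustained activation of ten positives fires once (counter reset)
  expect_equal(voting_queue_detections(rep(1, 10), ends), ends[5])
  # runs of four never fire
  expect_equal(voting_queue_detections(c(1, 1, 1, 1, 0, 1, 1, 1, 1, 0),
                                       ends), numeric(0))
  expect_error(voting_queue_detections(c(1, 0), ends), "length")
})

test_that("offline CV tests each trial exactly once and aces oracle data", {
  # constructed features: class-separated, 4 trials x 2 cycles x 2 windows
  # x 4 epochs
  set.seed(21)
  n_tr <- 4
  rows <- expand.grid(ep = 1:4, label = c(0L, 1L), cycle = 1:2,
                      trial = seq_len(n_tr))
  feat <- matrix(rnorm(nrow(rows) * 2, mean = 3 * rows$label, sd = 0.2),
                 ncol = 2)
  win <- paste(rows$trial, rows$cycle, rows$label)
  per <- pedalbci:::.offline_cv_core(feat, rows$label, rows$trial, win, "4s")
  expect_identical(sort(per$trial), seq_len(n_tr))
  expect_equal(per$tpr, rep(1, n_tr))
  expect_equal(per$acc, rep(1, n_tr))
  expect_equal(per$fp_per_min, rep(0, n_tr))
})

test_that("random labels give chance-level detection over many seeds", {
  # featureless problem: window = one epoch, labels coin-flipped per window
  tprs <- fprs <- numeric(20)
  for (s in seq_len(20)) {
    set.seed(400 + s)
    rows <- expand.grid(win = 1:10, trial = 1:6)
    lab <- as.integer(rep(rbinom(30, 1, 0.5), length.out = nrow(rows)))
    # balanced relabel: force half 1s within each trial
    lab <- as.integer(unlist(lapply(split(seq_len(nrow(rows)), rows$trial),
                                    function(i) sample(rep(0:1, 5)))))
    feat <- matrix(rnorm(nrow(rows) * 3), ncol = 3)
    win <- paste(rows$trial, rows$win)
    per <- pedalbci:::.offline_cv_core(feat, lab, rows$trial, win, "4s")
    tprs[s] <- mean(per$tpr)
  }
  expect_gt(mean(tprs), 0.40)
  expect_lt(mean(tprs), 0.60)
})

test_that("the pseudo-online pipeline recovers a strong synthetic ERD", {
  ses <- shared_tiny_session()
  r <- evaluate_pseudo_online(ses, "D", 4, "2s", train_trials = 1:3)
  expect_s3_class(r$result, "evaluation_result")
  # detections only after the 5th epoch of a cycle is available
  if (nrow(r$detections) > 0) {
    cyc_start <- ses$events$cycle_start_s[
      match(paste(r$detections$trial, r$detections$cycle),
            paste(ses$events$trial, ses$events$cycle))]
    expect_true(all(r$detections$time >= cyc_start + 1 + 4 * 0.2))
  }
  expect_gt(r$result$wd, 0.3)
  # reproducibility of the full evaluation
  r2 <- evaluate_pseudo_online(ses, "D", 4, "2s", train_trials = 1:3)
  expect_equal(r$detections, r2$detections)
  expect_equal(r$result$wd, r2$result$wd)
})

test_that("offline evaluation on the shared session is coherent", {
  ses <- shared_tiny_session()
  r <- evaluate_offline(ses, "C", 4, "2s")
  per <- r$per_split
  # every trial tested exactly once; decisions per fold = 2 x cycles
  expect_identical(sort(per$trial), sort(unique(ses$events$trial)))
  expect_true(all(per$n_events == 2))
  expect_gte(r$tpr, 0)
  expect_lte(r$tpr, 1)
  expect_equal(r$wd, compute_wd(r$tpr, r$acc, r$fp_per_min,
                                wd_weights("offline", "2s")))
})
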