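session_from <- function(correct, decision = NULL, trial_s = 5, pause_s = 3) {
  n <- length(correct)
  if (is.null(decision)) decision <- ifelse(correct, "class2", "class1")
  t0 <- (seq_len(n) - 1) * (trial_s + pause_s)
  oc <- data.frame(cue = rep(1L, n), accumulated = ifelse(correct, 1, -1),
                   decision = decision,
                   correct = ifelse(decision == "noDecision", NA, correct),
                   t_start = t0, t_end = t0 + trial_s)
  hybridbci:::new_session(oc, "CopyTask", NULL)
}

test_that("binary accuracy counts correct trials and blocks", {
  log <- session_from(c(rep(TRUE, 15), rep(FALSE, 5)))
  res <- binary_accuracy(log)
  expect_equal(res$accuracy, 0.75)
  expect_identical(res$n_trials, 20L)
  res1 <- binary_accuracy(session_from(rep(TRUE, 20)))
  expect_equal(res1$accuracy, 1)
  # 45 trials -> blocks of >= 20: two blocks
  res2 <- binary_accuracy(session_from(rep(c(TRUE, FALSE), length.out = 45)))
  expect_identical(nrow(res2$blocks), 2L)
  expect_true(all(res2$blocks$n >= 20))
})

test_that("a symmetric random scorer sits at the 50% chance level", {
  set.seed(30)
  correct <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  res <- binary_accuracy(session_from(correct))
  band <- 1.96 * sqrt(0.25 / 1000)
  expect_gt(res$accuracy, 0.5 - band - 0.001)
  expect_lt(res$accuracy, 0.5 + band + 0.001)
})

test_that("exact binomial chance test matches brute-force tail sums", {
  # oracle: full enumeration of the binomial tail at p = 1/2
  tail_sum <- function(k, n) sum(choose(n, k:n)) / 2^n
  expect_equal(chance_test(15, 20)$p_value, tail_sum(15, 20))
  expect_equal(round(chance_test(15, 20)$p_value, 4), 0.0207)
  expect_true(chance_test(15, 20)$significant)
  expect_equal(chance_test(10, 20)$p_value, tail_sum(10, 20))
  expect_equal(round(chance_test(10, 20)$p_value, 3), 0.588)
  expect_false(chance_test(10, 20)$significant)
  expect_equal(chance_test(20, 20)$p_value, 2^-20)
  expect_error(chance_test(21, 20), "exceeds")
  # monotone: more correct never increases p
  ps <- vapply(0:20, function(k) chance_test(k, 20)$p_value, 0)
  expect_true(all(diff(ps) <= 0))
  # chi-squared cross-check agrees on significance at these counts
  expect_true(chance_test(16, 20)$p_value_chisq < 0.05)
})

test_that("Wolpaw bits follow the closed form", {
  expect_identical(wolpaw_bits(1, 2), 1)
  expect_identical(wolpaw_bits(0.5, 2), 0)
  # direct evaluation: 1 + 0.9 log2(0.9) + 0.1 log2(0.1) = 0.5310044
  expect_equal(wolpaw_bits(0.9, 2), 0.5310044, tolerance = 1e-6)
  expect_equal(wolpaw_bits(0, 2), 1)    # perfectly anti-correlated
  # strictly increasing on (0.5, 1]
  p <- seq(0.51, 1, by = 0.01)
  expect_true(all(diff(wolpaw_bits(p, 2)) > 0))
  # N-class generalization at P = 1 is log2(N)
  expect_equal(wolpaw_bits(1, 4), 2)
})

test_that("pause-aware ITR divides by all elapsed time", {
  expect_equal(itr_with_pauses(list(n_decided = 10, n_correct = 10,
                                    elapsed_s = 300)), 2)
  # five extra noDecision trials add 150 s: 10 bits / 7.5 min
  expect_equal(itr_with_pauses(list(n_decided = 10, n_correct = 10,
                                    elapsed_s = 450)), 10 / 7.5)
  expect_equal(itr_with_pauses(list(n_decided = 0, n_correct = 0,
                                    elapsed_s = 100)), 0)
  expect_error(itr_with_pauses(list(n_decided = 1, n_correct = 1,
                                    elapsed_s = 0)), "elapsed")
  # monotone decreasing in added pause time on a session object
  log <- session_from(rep(TRUE, 10))
  base <- itr_with_pauses(log)
  log$pauses_extra <- 60
  expect_lt(itr_with_pauses(log), base)
})

test_that("noDecision trials cost time but no selections", {
  correct <- rep(TRUE, 10)
  log_all <- session_from(correct)
  log_nd <- session_from(c(correct, rep(TRUE, 5)),
                         decision = c(ifelse(correct, "class2", "class1"),
                                      rep("noDecision", 5)))
  r1 <- binary_accuracy(log_all)
  r2 <- binary_accuracy(log_nd)
  expect_identical(r2$n_nodecision, 5L)
  expect_equal(r2$accuracy, 1)          # decided trials only
  expect_lt(r2$itr_bits_per_min, r1$itr_bits_per_min)
})

test_that("cross-validated accuracy separates planted classes, not noise", {
  gen <- generate_recording(synthetic_config(n_trials = 25, snr = 2,
                                             seed = 31))
  osc <- bandpass(gen$recording,
                  filter_spec("bandpass", 5, band(8, 12), "causal"))
  ep <- epoch(osc, c("class1", "class2"), c(0, 5000))
  cv <- crossval_accuracy(ep, c(500, 5000), seed = 1)
  expect_gte(cv$accuracy, 0.95)
  expect_identical(cv$k, 5L)
  # deterministic under a fixed fold seed
  cv2 <- crossval_accuracy(ep, c(500, 5000), seed = 1)
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)
  # label shuffling destroys it (single check; the full reshuffle suite
  # runs in the acceptance tests)
  eps <- ep
  set.seed(2)
  eps$labels <- sample(ep$labels)
  cvs <- crossval_accuracy(eps, c(500, 5000), seed = 1)
  band <- 1.96 * sqrt(0.25 / length(ep$labels))
  expect_lt(abs(cvs$accuracy - 0.5), band + 0.1)
})

test_that("Welch PSD satisfies Parseval and flags short segments", {
  set.seed(32)
  x <- rnorm(4096)
  w <- welch_psd(x, fs = 100, nperseg = 512)
  df <- w$freq[2] - w$freq[1]
  expect_equal(sum(w$psd) * df, stats::var(x), tolerance = 0.02)
  expect_error(welch_psd(rnorm(100), 100, nperseg = 256), "shorter")
})

test_that("spectral screening localizes a planted idle rhythm", {
  set.seed(33)
  fs <- 100; n <- 6000
  sig <- matrix(rnorm(4 * n), 4, n)
  # 10 Hz rhythm on channels 3-4 during the second half (eyes closed)
  closed <- (n / 2 + 1):n
  t <- closed / fs
  sig[3, closed] <- sig[3, closed] + 2 * sin(2 * pi * 10 * t)
  sig[4, closed] <- sig[4, closed] + 2 * sin(2 * pi * 10 * t + 1)
  rec <- recording(sig, fs)
  segs <- data.frame(start = c(0, n / 2), end = c(n / 2, n),
                     condition = c("eyes-open", "eyes-closed"))
  scr <- spectral_screening(rec, segs)
  expect_gt(scr[["eyes-closed"]]$alpha_power[3],
            2 * scr[["eyes-open"]]$alpha_power[3])
  expect_gt(scr[["eyes-closed"]]$alpha_power[4],
            2 * scr[["eyes-open"]]$alpha_power[4])
  # channels without the planted rhythm are comparable across conditions
  r12 <- scr[["eyes-closed"]]$alpha_power[1:2] /
    scr[["eyes-open"]]$alpha_power[1:2]
  expect_true(all(r12 > 0.5 & r12 < 2))
  expect_error(spectral_screening(rec, data.frame(start = 0, end = 50,
                                                  condition = "tiny")),
               "shorter")
})
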