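test_that("accumulation is the mean of the frame scores", {
  expect_equal(accumulate(rep(0.4, 7)), 0.4)
  expect_equal(accumulate(c(-2, 2)), 0)
  expect_equal(accumulate(c(0.1, 0.3, 0.2)), 0.2)
  expect_error(accumulate(numeric(0)), "no frame")
})

# one fitted model + one held-out stream shared by the online tests
fit_and_stream <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    train <- generate_recording(synthetic_config(n_trials = 25, snr = 2,
                                                 seed = 50))
    model <- hybrid_bci(train$recording, bci_config(seed = 1))
    test <- generate_recording(synthetic_config(n_trials = 20, snr = 2,
                                                seed = 51))
    cache <<- list(model = model, test = test)
    cache
  }
})

test_that("CopyTask decodes a high-SNR synthetic stream", {
  fs <- fit_and_stream()
  out <- run_copy_task(fs$test$recording, fs$model)
  expect_s3_class(out$log, "bci_session")
  expect_identical(nrow(out$log$outcomes), 40L)
  expect_gte(mean(out$log$outcomes$correct), 0.9)
  # correctness is sign-based: no noDecision in CopyTask
  expect_true(all(out$log$outcomes$decision != "noDecision"))
  # adaptation ran after every trial for both branches
  expect_identical(out$log$n_adapt, 80L)
  expect_false(identical(out$model$lda_osc$w, fs$model$lda_osc$w))
})

test_that("a frozen pipeline without adaptation is bit-reproducible", {
  fs <- fit_and_stream()
  o1 <- run_copy_task(fs$test$recording, fs$model, adaptation = FALSE)
  o2 <- run_copy_task(fs$test$recording, fs$model, adaptation = FALSE)
  expect_identical(o1$log$outcomes, o2$log$outcomes)
  expect_identical(o1$model$lda_osc$w, fs$model$lda_osc$w)
  expect_identical(o1$log$n_adapt, 0L)
})

test_that("label-shuffled streams are decoded at chance", {
  cfg <- synthetic_config(n_trials = 20, snr = 2, seed = 52)
  gen <- generate_recording(cfg)
  # break the label-signal link: keep signals, permute the cue labels
  rec <- gen$recording
  cues <- rec$markers$label %in% c("class1", "class2")
  set.seed(1)
  rec$markers$label[cues] <- sample(rec$markers$label[cues])
  fs <- fit_and_stream()
  out <- run_copy_task(rec, fs$model, adaptation = FALSE)
  band <- 1.96 * sqrt(0.25 / nrow(out$log$outcomes))
  expect_lt(abs(mean(out$log$outcomes$correct) - 0.5), band + 0.15)
})

test_that("adaptation tracks a drifting stream better than a frozen model", {
  diffs <- vapply(1:4, function(s) {
    train <- generate_recording(synthetic_config(n_trials = 20, snr = 1,
                                                 seed = 500 + s))
    model <- hybrid_bci(train$recording, bci_config(seed = s))
    drift <- generate_recording(synthetic_config(n_trials = 25, snr = 1,
                                                 drift_rate = 3,
                                                 seed = 600 + s))
    on <- mean(run_copy_task(drift$recording, model)$log$outcomes$correct)
    off <- mean(run_copy_task(drift$recording, model,
                              adaptation = FALSE)$log$outcomes$correct)
    on - off
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("trial clock bookkeeping matches the marker schedule", {
  fs <- fit_and_stream()
  out <- run_copy_task(fs$test$recording, fs$model, adaptation = FALSE)
  oc <- out$log$outcomes
  expect_true(all(oc$t_end > oc$t_start))
  expect_true(all(diff(oc$t_start) > 0))
  # trials do not overlap; elapsed = trials + pauses
  expect_true(all(utils::head(oc$t_end, -1) <= utils::tail(oc$t_start, -1)))
  elapsed <- max(oc$t_end) - min(oc$t_start)
  pauses <- sum(utils::tail(oc$t_start, -1) - utils::head(oc$t_end, -1))
  expect_equal(sum(oc$t_end - oc$t_start) + pauses, elapsed,
               tolerance = 1e-9)
})

test_that("an infinite threshold yields only noDecisions and no actions", {
  fs <- fit_and_stream()
  su <- scripted_user(rep(1:2, 8), synthetic_config(n_trials = 8, snr = 2,
                                                    seed = 53))
  out <- run_free_mode(su$recording, fs$model,
                       policy = decision_policy(Inf))
  expect_true(all(out$log$outcomes$decision == "noDecision"))
  expect_identical(sum(out$game$board != 0L), 0L)
  expect_identical(out$log$n_adapt, 0L)
})

test_that("FreeMode turns decoded intents into game actions", {
  fs <- fit_and_stream()
  # script: select column 2 (two cursor advances), then drop the coin
  intents <- c(1L, 1L, 2L)
  su <- scripted_user(intents, synthetic_config(n_trials = 3, snr = 4,
                                                seed = 54))
  out <- run_free_mode(su$recording, fs$model,
                       policy = decision_policy(0), opponent = NULL,
                       intents = intents)
  oc <- out$log$outcomes
  expect_identical(nrow(oc), 3L)
  expect_true(all(oc$decision != "noDecision"))
  expect_true(all(oc$correct))
  expect_identical(out$game$board[1, 3], 1L)    # coin in cursor column 2
  expect_identical(sum(out$game$board != 0L), 1L)
  # with an opponent, the heuristic answers each placement
  out2 <- run_free_mode(su$recording, fs$model,
                        policy = decision_policy(0), intents = intents)
  expect_identical(sum(out2$game$board == 2L), 1L)
})

test_that("noDecision trials spend time without producing selections", {
  fs <- fit_and_stream()
  su <- scripted_user(rep(1:2, 10), synthetic_config(n_trials = 10, snr = 2,
                                                     seed = 55))
  gated <- run_free_mode(su$recording, fs$model,
                         policy = decision_policy(1e3),
                         intents = rep(1:2, 10))
  open <- run_free_mode(su$recording, fs$model,
                        policy = decision_policy(0),
                        intents = rep(1:2, 10))
  n_gated <- sum(gated$log$outcomes$decision != "noDecision")
  n_open <- sum(open$log$outcomes$decision != "noDecision")
  expect_lt(n_gated, n_open)
  # same elapsed time, fewer selections -> lower ITR for the gated run
  if (n_gated > 0) {
    expect_lt(itr_with_pauses(gated$log), itr_with_pauses(open$log))
  }
})

test_that("serialized models reload to the identical classifier", {
  fs <- fit_and_stream()
  path <- file.path(withr::local_tempdir(), "model.json")
  save_model(fs$model, path)
  back <- load_model(path)
  expect_equal(back$lda_osc$w, fs$model$lda_osc$w, tolerance = 1e-12)
  expect_equal(back$csp$filters, fs$model$csp$filters, tolerance = 1e-12)
  expect_equal(back$meta$w_osc, fs$model$meta$w_osc)
  pr1 <- predict(fs$model, fs$test$recording)
  pr2 <- predict(back, fs$test$recording)
  expect_equal(pr1$combined, pr2$combined, tolerance = 1e-9)
})

test_that("the fitted model exposes the standard S3 surface", {
  fs <- fit_and_stream()
  m <- fs$model
  expect_output(print(m), "two-branch")
  s <- summary(m)
  expect_output(print(s), "CV accuracy")
  expect_equal(sum(coef(m, "meta")), 1)
  expect_length(coef(m, "slow"), 17)       # 16 channels + bias
  pr <- predict(m, fs$test$recording, type = "class")
  expect_true(all(pr %in% 1:2))
  dec <- predict(m, fs$test$recording, type = "decision")
  expect_true(all(dec %in% c("select_next_column", "place_coin",
                             "noDecision")))
  pdf(NULL)
  expect_silent(plot(m))
  dev.off()
})
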