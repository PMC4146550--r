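#' Accumulate frame-wise classifier outputs into a trial output
#'
#' The continuous feedback signal is evaluated on a sliding window several
#' times per second; the trial's final output is the mean of those frame
#' scores over the classification interval. A trial is judged by where this
#' accumulated output points at the end of the trial.
#'
#' @param scores time-ordered numeric frame scores of one trial.
#' @return Their mean.
#' @export
accumulate <- function(scores) {
  if (length(scores) == 0) stop("no frame scores to accumulate")
  mean(scores)
}

# causal branch filtering of a continuous stream; returns channel x sample
# matrices for both branches
stream_filter <- function(rec, cfg) {
  osc <- bandpass(rec, filter_spec("bandpass", cfg$filter_order,
                                   cfg$erd_band, "causal"))
  slow <- bandpass(rec, filter_spec("bandpass", cfg$filter_order,
                                    cfg$lrp_band, "causal"))
  list(osc = osc$signal, slow = slow$signal)
}

# frame-wise combined scores for one trial starting at 0-based sample s0.
# Everything is causal: the oscillatory score uses a sliding frame_len
# window; the slow score uses the trained LRP interval clipped to the time
# elapsed so far (its feature needs >= 200 ms of that interval). Before slow
# evidence exists the combined output falls back to the oscillatory branch.
trial_frames <- function(model, sigs, s0, fs) {
  cfg <- model$config
  ends <- seq(cfg$osc_interval[1] + cfg$frame_len, cfg$osc_interval[2],
              by = cfg$frame_step)
  w <- model$csp$filters[model$csp$selected, , drop = FALSE]
  # causal baseline from the pre-onset interval
  b0 <- s0 + round(cfg$baseline[1] * fs / 1000)
  b1 <- s0 + round(cfg$baseline[2] * fs / 1000)
  bl <- rowMeans(sigs$slow[, (b0 + 1L):b1, drop = FALSE])
  l0 <- s0 + round(cfg$lrp_interval[1] * fs / 1000)
  l1 <- s0 + round(cfg$lrp_interval[2] * fs / 1000)
  meta <- model$meta
  out <- vapply(ends, function(e) {
    a <- s0 + round((e - cfg$frame_len) * fs / 1000)
    b <- s0 + round(e * fs / 1000)
    seg_o <- w %*% sigs$osc[, (a + 1L):b, drop = FALSE]
    v <- pmax(apply(seg_o, 1, stats::var), .Machine$double.eps)
    z_osc <- lda_score(model$lda_osc, log(v)) / meta$scale_osc
    lb <- min(b, l1)
    if (lb - l0 >= round(0.2 * fs)) {
      feat <- rowMeans(sigs$slow[, (l0 + 1L):lb, drop = FALSE]) - bl
      z_slow <- lda_score(model$lda_slow, feat) / meta$scale_slow
      switch(meta$active_output,
             combined = meta$w_osc * z_osc + meta$w_slow * z_slow,
             oscillatory = z_osc,
             slow = z_slow)
    } else {
      if (meta$active_output == "slow") NA_real_ else z_osc
    }
  }, 0)
  out[!is.na(out)]
}

# trial-level feature vectors used for supervised adaptation
trial_features <- function(model, sigs, s0, fs) {
  cfg <- model$config
  o0 <- s0 + round(cfg$osc_interval[1] * fs / 1000)
  o1 <- s0 + round(cfg$osc_interval[2] * fs / 1000)
  w <- model$csp$filters[model$csp$selected, , drop = FALSE]
  seg <- w %*% sigs$osc[, (o0 + 1L):o1, drop = FALSE]
  x_osc <- log(pmax(apply(seg, 1, stats::var), .Machine$double.eps))
  b0 <- s0 + round(cfg$baseline[1] * fs / 1000)
  b1 <- s0 + round(cfg$baseline[2] * fs / 1000)
  bl <- rowMeans(sigs$slow[, (b0 + 1L):b1, drop = FALSE])
  l0 <- s0 + round(cfg$lrp_interval[1] * fs / 1000)
  l1 <- s0 + round(cfg$lrp_interval[2] * fs / 1000)
  x_slow <- rowMeans(sigs$slow[, (l0 + 1L):l1, drop = FALSE]) - bl
  list(osc = x_osc, slow = x_slow)
}

new_session <- function(outcomes, mode, config, n_adapt = 0L,
                        pauses_extra = 0) {
  structure(list(outcomes = outcomes, mode = mode, config = config,
                 n_adapt = n_adapt, pauses_extra = pauses_extra),
            class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  oc <- x$outcomes
  cat(sprintf("<bci_session> %s: %d trials, %d noDecision, %d adaptations\n",
              x$mode, nrow(oc), sum(oc$decision == "noDecision"), x$n_adapt))
  if (any(!is.na(oc$correct)))
    cat(sprintf("  accuracy (scored trials): %.1f%%\n",
                100 * mean(oc$correct, na.rm = TRUE)))
  invisible(x)
}

#' Run a cued, labeled CopyTask session
#'
#' The supervised closed-loop mode: each cued trial is scored frame by frame
#' with causal filtering, the accumulated output is compared against the cue
#' by sign (the decision threshold plays no role in CopyTask correctness),
#' and after every trial both branch LDAs are adapted with the known label.
#' No game actions are emitted.
#'
#' @param stream a cued [recording()] (markers `class1`/`class2`).
#' @param model a fitted [hybrid_bci()].
#' @param adaptation logical: per-trial supervised adaptation (default TRUE).
#' @param rate adaptation rate (default the model config's).
#' @return List `log` (a `bci_session`; one outcome row per trial with cue,
#'   accumulated output, sign-based decision and correctness, trial clock)
#'   and `model` (the possibly adapted classifier).
#' @export
run_copy_task <- function(stream, model, adaptation = TRUE, rate = NULL) {
  stopifnot(inherits(stream, "bci_recording"), inherits(model, "hybrid_bci"))
  cfg <- model$config
  fs <- stream$fs
  sigs <- stream_filter(stream, cfg)
  cues <- stream$markers[stream$markers$label %in% c("class1", "class2"), ,
                         drop = FALSE]
  trial_samp <- round(cfg$epoch_window[2] * fs / 1000)
  ok <- cues$sample + trial_samp <= ncol(stream$signal) &
    cues$sample + round(cfg$baseline[1] * fs / 1000) >= 0
  if (any(!ok)) warning("stream shorter than cue schedule; ",
                        sum(!ok), " trial(s) truncated")
  cues <- cues[ok, , drop = FALSE]
  st_osc <- adaptation_state(rate %||% cfg$adaptation_rate,
                             enabled = adaptation)
  st_slow <- st_osc
  n_adapt <- 0L
  rows <- vector("list", nrow(cues))
  for (k in seq_len(nrow(cues))) {
    s0 <- cues$sample[k]
    y <- if (cues$label[k] == "class1") 1L else 2L
    acc <- accumulate(trial_frames(model, sigs, s0, fs))
    decision <- if (acc > 0) "class2" else "class1"
    rows[[k]] <- data.frame(
      cue = y, accumulated = acc, decision = decision,
      correct = (acc > 0) == (y == 2L),
      t_start = s0 / fs, t_end = (s0 + trial_samp) / fs)
    if (adaptation) {
      xs <- trial_features(model, sigs, s0, fs)
      up <- adapt(model$lda_osc, st_osc, xs$osc, y)
      model$lda_osc <- up$model; st_osc <- up$state
      up <- adapt(model$lda_slow, st_slow, xs$slow, y)
      model$lda_slow <- up$model; st_slow <- up$state
      n_adapt <- n_adapt + 2L
    }
  }
  log <- new_session(do.call(rbind, rows), "CopyTask", cfg, n_adapt)
  list(log = log, model = model)
}

#' Run a threshold-gated FreeMode session driving the game
#'
#' The free-control mode: cues are question marks (class unknown), the
#' accumulated output is gated by the decision policy -- an action is
#' emitted only when `|accumulated| > theta`, otherwise the trial is a
#' noDecision -- and every decided action is applied to the Connect-4 game,
#' with the computer opponent replying after each successful coin placement.
#' Adaptation is never performed in FreeMode (labels are unknown).
#' Attempted drops into a full column are rejected by the game and logged;
#' the user must re-select.
#'
#' @param stream a [recording()] with `question` cue markers.
#' @param model a fitted [hybrid_bci()].
#' @param policy a [decision_policy()] (default the model's).
#' @param game a [new_game()] (user is player 1).
#' @param opponent function `game -> column` for player 2 (default
#'   [heuristic_move()]); `NULL` for a user-only board.
#' @param intents optional true intended classes (1 = select, 2 = place)
#'   for scoring decided trials in evaluation.
#' @return List `log` (a `bci_session`) and `game` (final state).
#' @export
run_free_mode <- function(stream, model, policy = NULL, game = new_game(),
                          opponent = heuristic_move, intents = NULL) {
  stopifnot(inherits(stream, "bci_recording"), inherits(model, "hybrid_bci"))
  cfg <- model$config
  policy <- policy %||% model$policy
  fs <- stream$fs
  sigs <- stream_filter(stream, cfg)
  cues <- stream$markers[stream$markers$label == "question", , drop = FALSE]
  trial_samp <- round(cfg$epoch_window[2] * fs / 1000)
  cues <- cues[cues$sample + trial_samp <= ncol(stream$signal), , drop = FALSE]
  rows <- vector("list", nrow(cues))
  for (k in seq_len(nrow(cues))) {
    s0 <- cues$sample[k]
    acc <- accumulate(trial_frames(model, sigs, s0, fs))
    action <- decide(policy, acc)
    if (action != "noDecision" && game$status == "ongoing") {
      placed_before <- sum(game$heights)
      game <- apply_action(game, action)
      if (action == "place_coin" && sum(game$heights) > placed_before &&
          game$status == "ongoing" && !is.null(opponent)) {
        game <- drop_coin(game, opponent(game))
      }
    }
    correct <- if (is.null(intents)) NA else {
      if (action == "noDecision") NA
      else (action == "place_coin") == (intents[k] == 2L)
    }
    rows[[k]] <- data.frame(
      cue = if (is.null(intents)) NA_integer_ else intents[k],
      accumulated = acc, decision = action, correct = correct,
      t_start = s0 / fs, t_end = (s0 + trial_samp) / fs)
  }
  log <- new_session(do.call(rbind, rows), "FreeMode", cfg, n_adapt = 0L)
  list(log = log, game = game)
}
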