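#' Weighted meta-combination of the two branch classifiers
#'
#' The application receives the oscillatory-branch output, the
#' slow-potential-branch output, and their individually weighted sum; the
#' experimenter can pin `active_output` to a single branch. Member scores
#' are divided by the standard deviation of their training-set outputs
#' before weighting, so the weights compare like with like across feature
#' scales.
#'
#' @param w_osc,w_slow nonnegative weights; normalized to sum to 1.
#' @param scale_osc,scale_slow training-score standard deviations used to
#'   standardize each member's output (default 1 = already commensurate).
#' @param active_output which signal the application consumes.
#' @return A `bci_meta` list.
#' @export
meta_classifier <- function(w_osc = 0.5, w_slow = 0.5,
                            scale_osc = 1, scale_slow = 1,
                            active_output = c("combined", "oscillatory", "slow")) {
  active_output <- match.arg(active_output)
  if (w_osc < 0 || w_slow < 0 || (w_osc + w_slow) <= 0)
    stop("weights must be nonnegative with positive sum")
  s <- w_osc + w_slow
  structure(list(w_osc = w_osc / s, w_slow = w_slow / s,
                 scale_osc = scale_osc, scale_slow = scale_slow,
                 active_output = active_output),
            class = "bci_meta")
}

#' Combine the two branch scores
#'
#' @param meta a [meta_classifier()].
#' @param s_osc,s_slow raw member scores (vectors allowed).
#' @return The active output: standardized weighted sum, or a single
#'   standardized branch score.
#' @export
combine <- function(meta, s_osc, s_slow) {
  stopifnot(inherits(meta, "bci_meta"))
  zo <- s_osc / meta$scale_osc
  zs <- s_slow / meta$scale_slow
  switch(meta$active_output,
         combined = meta$w_osc * zo + meta$w_slow * zs,
         oscillatory = zo,
         slow = zs)
}

#' Threshold-gated decision policy
#'
#' Gates the accumulated classifier output: an action is only emitted when
#' the predefined threshold `theta` is exceeded; otherwise the trial is a
#' "noDecision" (no action, but time is still spent). The boundary
#' `|accumulated| == theta` maps to noDecision (closed interval).
#'
#' @param theta nonnegative threshold on the accumulated output.
#' @param action_a,action_b action names for negative (class-1) and positive
#'   (class-2) outputs.
#' @return A `bci_policy` list.
#' @export
decision_policy <- function(theta = 0, action_a = "select_next_column",
                            action_b = "place_coin") {
  stopifnot(theta >= 0)
  structure(list(theta = theta, action_a = action_a, action_b = action_b),
            class = "bci_policy")
}

#' Apply a decision policy to an accumulated output
#'
#' @param policy a [decision_policy()].
#' @param accumulated final scalar trial output.
#' @return `policy$action_a` if `accumulated < -theta`, `policy$action_b` if
#'   `accumulated > theta`, otherwise `"noDecision"`.
#' @export
decide <- function(policy, accumulated) {
  stopifnot(inherits(policy, "bci_policy"))
  if (is.na(accumulated)) return("noDecision")
  if (accumulated < -policy$theta) policy$action_a
  else if (accumulated > policy$theta) policy$action_b
  else "noDecision"
}

#' Calibrate the decision threshold from labeled outcomes
#'
#' Chooses the smallest theta for which the precision on decided trials
#' reaches `target_precision`, over a grid of candidate thresholds taken
#' from the observed absolute scores. Falls back to the largest candidate
#' if the target is unreachable.
#'
#' @param scores accumulated outputs of labeled trials.
#' @param labels true classes (1 = negative, 2 = positive).
#' @param target_precision desired fraction correct among decided trials
#'   (default 0.8).
#' @return A [decision_policy()] with the calibrated theta.
#' @export
calibrate_theta <- function(scores, labels, target_precision = 0.8) {
  stopifnot(length(scores) == length(labels))
  cand <- sort(unique(c(0, abs(scores))))
  correct_sign <- sign(scores) == ifelse(labels == 1, -1, 1)
  for (th in cand) {
    decided <- abs(scores) > th
    if (!any(decided)) break
    if (mean(correct_sign[decided]) >= target_precision)
      return(decision_policy(theta = th))
  }
  decision_policy(theta = cand[length(cand)])
}
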