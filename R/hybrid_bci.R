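#' Pipeline configuration for the hybrid classifier
#'
#' Collects every tunable of the two-branch pipeline in one serializable
#' object. Defaults mirror the standard setup: an 8-12 Hz oscillatory band
#' filtered with an order-5 Butterworth, covariance/feature interval from
#' 500 ms to trial end, a 0.2-4 Hz slow-potential band with a 300 ms
#' pre-onset baseline, 6 CSP components, analytic shrinkage, per-trial
#' adaptation rate 0.03, and a sliding 1 s scoring window advanced every
#' 100 ms for continuous feedback.
#'
#' @param erd_band oscillatory [band()] (default 8-12 Hz).
#' @param lrp_band slow-potential [band()] (default 0.2-4 Hz).
#' @param filter_order Butterworth order (default 5).
#' @param filter_mode `"causal"` (matches the online path; default) or
#'   `"zero-phase"` for offline-only analyses.
#' @param epoch_window trial epoch in ms relative to cue, default
#'   `c(-300, 5000)` (includes the baseline interval).
#' @param osc_interval ms window for CSP covariance and log-variance.
#' @param lrp_interval ms window for slow-potential mean amplitudes.
#' @param baseline ms interval for channel-wise baselining.
#' @param n_csp number of CSP components (default 6).
#' @param gamma fixed LDA shrinkage or `NULL` for the analytic estimate.
#' @param adaptation_rate per-trial supervised update rate (default 0.03).
#' @param cv_folds folds for the branch-weight cross-validation (default 5).
#' @param theta decision threshold for FreeMode gating (default 0).
#' @param frame_len,frame_step online scoring window and step, ms.
#' @param seed RNG seed for fold assignment.
#' @return A `bci_config` list.
#' @export
bci_config <- function(erd_band = band(8, 12, "alpha"),
                       lrp_band = band(0.2, 4, "slow"),
                       filter_order = 5,
                       filter_mode = c("causal", "zero-phase"),
                       epoch_window = c(-300, 5000),
                       osc_interval = c(500, 5000),
                       lrp_interval = c(2500, 4000),
                       baseline = c(-300, 0),
                       n_csp = 6, gamma = NULL,
                       adaptation_rate = 0.03, cv_folds = 5,
                       theta = 0, frame_len = 1000, frame_step = 100,
                       seed = 1) {
  filter_mode <- match.arg(filter_mode)
  structure(as.list(environment()), class = "bci_config")
}

#' Fit the hybrid two-branch motor-imagery classifier
#'
#' The decision core of the system. From a labeled (cued) recording it fits:
#' \describe{
#'   \item{oscillatory branch}{band-pass filter in `erd_band`, Common
#'     Spatial Patterns over `osc_interval`, log-variance features, shrinkage
#'     LDA -- captures event-related desynchronization and beta rebound.}
#'   \item{slow branch}{0.2-4 Hz band-pass, 300 ms pre-onset baseline,
#'     channel-wise mean amplitudes over `lrp_interval`, shrinkage LDA --
#'     captures the lateralized readiness potential.}
#' }
#' Each branch's output is standardized by its training-score spread, and
#' the meta-combination weights the two standardized scores by
#' `max(0, CV accuracy - 0.5)` per branch (renormalized), so a branch that
#' carries no information is switched off. The application can also be
#' pinned to a single branch via `active_output`.
#'
#' @param rec a cued [recording()] (markers `class1` / `class2`).
#' @param config a [bci_config()].
#' @param active_output `"combined"` (default), `"oscillatory"` or `"slow"`.
#' @return An object of class `hybrid_bci`: branch models (`csp`,
#'   `lda_osc`, `lda_slow`), `meta`, `policy`, per-branch `cv` summaries,
#'   `config`, `channel_labels`, `n_trials`.
#' @seealso [predict.hybrid_bci()], [run_copy_task()], [run_free_mode()]
#' @export
hybrid_bci <- function(rec, config = bci_config(),
                       active_output = c("combined", "oscillatory", "slow")) {
  stopifnot(inherits(rec, "bci_recording"), inherits(config, "bci_config"))
  active_output <- match.arg(active_output)
  ep <- branch_epochs(rec, config)
  labs <- ep$osc$labels
  if (length(unique(stats::na.omit(labs))) < 2)
    stop("training recording must contain cues of both classes (labels)")

  bank <- fit_csp(ep$osc, config$osc_interval, config$n_csp)
  X_osc <- csp_logvar(ep$osc, bank, config$osc_interval)
  lda_osc <- train_shrinkage_lda(X_osc, labs, gamma = config$gamma)
  X_slow <- lrp_features(ep$slow, config$lrp_interval)
  lda_slow <- train_shrinkage_lda(X_slow, labs, gamma = config$gamma)

  cv_osc <- crossval_accuracy(ep$osc, config$osc_interval, k = config$cv_folds,
                              n_select = config$n_csp, seed = config$seed)
  cv_slow <- crossval_lda(X_slow, labs, k = config$cv_folds,
                          gamma = config$gamma, seed = config$seed)
  w_osc <- max(0, cv_osc$accuracy - 0.5)
  w_slow <- max(0, cv_slow$accuracy - 0.5)
  if (w_osc + w_slow == 0) { w_osc <- 0.5; w_slow <- 0.5 }
  meta <- meta_classifier(
    w_osc, w_slow,
    scale_osc = max(stats::sd(lda_score(lda_osc, X_osc)), 1e-12),
    scale_slow = max(stats::sd(lda_score(lda_slow, X_slow)), 1e-12),
    active_output = active_output)

  structure(list(csp = bank, lda_osc = lda_osc, lda_slow = lda_slow,
                 meta = meta, policy = decision_policy(config$theta),
                 cv = list(oscillatory = cv_osc, slow = cv_slow),
                 config = config, channel_labels = rec$channel_labels,
                 n_trials = length(labs)),
            class = "hybrid_bci")
}

# epoch the recording once per branch with that branch's filtering
branch_epochs <- function(rec, config, cue_labels = c("class1", "class2")) {
  osc_rec <- bandpass(rec, filter_spec("bandpass", config$filter_order,
                                       config$erd_band, config$filter_mode))
  slow_rec <- bandpass(rec, filter_spec("bandpass", config$filter_order,
                                        config$lrp_band, config$filter_mode))
  ep_osc <- epoch(osc_rec, cue_labels, config$epoch_window)
  ep_slow <- baseline_correct(epoch(slow_rec, cue_labels, config$epoch_window),
                              config$baseline)
  list(osc = ep_osc, slow = ep_slow)
}

# plain k-fold CV for a fixed feature matrix (slow branch)
crossval_lda <- function(X, y, k = 5, gamma = NULL, seed = 1) {
  set.seed(seed)
  k <- min(k, min(table(y)))
  folds <- integer(length(y))
  for (cl in 1:2) {
    i <- which(y == cl)
    folds[i] <- sample(rep(seq_len(k), length.out = length(i)))
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f; te <- folds == f
    m <- train_shrinkage_lda(X[tr, , drop = FALSE], y[tr], gamma = gamma)
    mean(ifelse(lda_score(m, X[te, , drop = FALSE]) > 0, 2L, 1L) == y[te])
  }, 0)
  list(accuracy = mean(acc), fold_accuracy = acc, sd = stats::sd(acc), k = k)
}

#' @export
print.hybrid_bci <- function(x, ...) {
  cat("<hybrid_bci> two-branch motor-imagery classifier\n")
  cat(sprintf("  trained on %d trials, %d channels\n", x$n_trials,
              length(x$channel_labels)))
  cat(sprintf("  oscillatory: %s, %d CSP components, gamma %.3f, CV accuracy %.1f%%\n",
              x$config$erd_band$name, length(x$csp$selected),
              x$lda_osc$gamma, 100 * x$cv$oscillatory$accuracy))
  cat(sprintf("  slow:        %s, %d channels, gamma %.3f, CV accuracy %.1f%%\n",
              x$config$lrp_band$name, x$lda_slow$dim,
              x$lda_slow$gamma, 100 * x$cv$slow$accuracy))
  cat(sprintf("  meta weights: %.2f oscillatory + %.2f slow (%s), theta = %g\n",
              x$meta$w_osc, x$meta$w_slow, x$meta$active_output,
              x$policy$theta))
  invisible(x)
}

#' @export
summary.hybrid_bci <- function(object, ...) {
  s <- list(
    n_trials = object$n_trials,
    cv_oscillatory = object$cv$oscillatory$accuracy,
    cv_slow = object$cv$slow$accuracy,
    eigenvalues = object$csp$eigenvalues[object$csp$selected],
    gamma = c(oscillatory = object$lda_osc$gamma,
              slow = object$lda_slow$gamma),
    weights = c(oscillatory = object$meta$w_osc, slow = object$meta$w_slow),
    theta = object$policy$theta)
  class(s) <- "summary.hybrid_bci"
  s
}

#' @export
print.summary.hybrid_bci <- function(x, ...) {
  cat("Hybrid two-branch BCI classifier\n")
  cat(sprintf("  training trials:       %d\n", x$n_trials))
  cat(sprintf("  CV accuracy:           oscillatory %.1f%%, slow %.1f%%\n",
              100 * x$cv_oscillatory, 100 * x$cv_slow))
  cat(sprintf("  CSP eigenvalues:       %s\n",
              paste(sprintf("%.3f", x$eigenvalues), collapse = " ")))
  cat(sprintf("  shrinkage gamma:       oscillatory %.3f, slow %.3f\n",
              x$gamma[1], x$gamma[2]))
  cat(sprintf("  meta weights:          %.2f / %.2f, theta = %g\n",
              x$weights[1], x$weights[2], x$theta))
  invisible(x)
}

#' @export
coef.hybrid_bci <- function(object, branch = c("meta", "oscillatory", "slow"),
                            ...) {
  branch <- match.arg(branch)
  switch(branch,
         meta = c(w_osc = object$meta$w_osc, w_slow = object$meta$w_slow),
         oscillatory = c(object$lda_osc$w, b = object$lda_osc$b),
         slow = stats::setNames(
           c(object$lda_slow$w, object$lda_slow$b),
           c(object$channel_labels, "b")))
}

#' Score new trials with a fitted hybrid classifier
#'
#' Re-applies the branch preprocessing to a new cued recording, extracts
#' both feature sets over the trained intervals, scores each branch and
#' combines them.
#'
#' @param object a fitted [hybrid_bci()].
#' @param newdata a [recording()] with cue markers (`class1`/`class2` or
#'   `question`).
#' @param type `"score"` (default; data.frame of branch and combined scores
#'   plus the sign-based class), `"class"` (integer vector) or `"decision"`
#'   (threshold-gated actions via the model's policy).
#' @param ... unused.
#' @return See `type`.
#' @export
predict.hybrid_bci <- function(object, newdata,
                               type = c("score", "class", "decision"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "bci_recording"))
  cfg <- object$config
  ep <- branch_epochs(newdata, cfg,
                      cue_labels = c("class1", "class2", "question"))
  X_osc <- csp_logvar(ep$osc, object$csp, cfg$osc_interval)
  X_slow <- lrp_features(ep$slow, cfg$lrp_interval)
  s_osc <- lda_score(object$lda_osc, X_osc)
  s_slow <- lda_score(object$lda_slow, X_slow)
  comb <- combine(object$meta, s_osc, s_slow)
  if (type == "class") return(ifelse(comb > 0, 2L, 1L))
  if (type == "decision")
    return(vapply(comb, function(s) decide(object$policy, s), ""))
  data.frame(s_osc = s_osc, s_slow = s_slow, combined = comb,
             class = ifelse(comb > 0, 2L, 1L),
             label = ep$osc$labels)
}

#' Plot the discriminative spatial patterns of a fitted model
#'
#' Shows the selected CSP scalp patterns (channel loadings per component)
#' and the slow-branch LDA channel weights as bar profiles over the montage
#' -- the 1-D equivalent of the scalp maps used to sanity-check that
#' discriminative activity is motor-topographic.
#'
#' @param x a fitted [hybrid_bci()].
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.hybrid_bci <- function(x, ...) {
  sel <- x$csp$selected
  old <- graphics::par(mfrow = c(1, length(sel) + 1),
                       mar = c(6, 2, 3, 0.5))
  on.exit(graphics::par(old))
  for (j in sel) {
    graphics::barplot(x$csp$patterns[, j], names.arg = x$channel_labels,
                      las = 2, cex.names = 0.6,
                      main = sprintf("CSP %d\nev %.2f", j,
                                     x$csp$eigenvalues[j]), ...)
  }
  graphics::barplot(x$lda_slow$w, names.arg = x$channel_labels, las = 2,
                    cex.names = 0.6, main = "slow-branch\nLDA weights", ...)
  invisible(x)
}
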