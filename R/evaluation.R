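#' Binary accuracy of a session, with block breakdown
#'
#' The fraction of correct trials. For CopyTask logs correctness is
#' sign-based and every labeled trial counts; for FreeMode logs only decided
#' trials (those that exceeded the threshold) enter the denominator, since
#' noDecision trials produce no action to score. With two balanced classes
#' chance level is 50%. Consecutive trials are additionally grouped into
#' blocks of at least `block_size` trials and scored per block.
#'
#' @param log a `bci_session` from [run_copy_task()] / [run_free_mode()].
#' @param block_size minimum trials per reported block (default 20).
#' @return A `bci_session_result` list: `n_trials`, `n_correct`,
#'   `n_nodecision`, `accuracy`, `p_value` (exact binomial vs 0.5),
#'   `p_value_chisq` (Pearson chi-squared cross-check), `significant`,
#'   `itr_bits_per_min`, `blocks` (data.frame).
#' @export
binary_accuracy <- function(log, block_size = 20) {
  stopifnot(inherits(log, "bci_session"))
  oc <- log$outcomes
  scored <- !is.na(oc$correct)
  if (!any(scored)) stop("no labeled (scorable) trials in this session")
  n_nodec <- sum(oc$decision == "noDecision")
  n_correct <- sum(oc$correct[scored])
  denom <- sum(scored)
  acc <- n_correct / denom
  ct <- chance_test(n_correct, denom)
  idx <- which(scored)
  nb <- max(1L, floor(length(idx) / block_size))
  bl <- split(idx, rep(seq_len(nb), each = ceiling(length(idx) / nb))[seq_along(idx)])
  blocks <- data.frame(
    block = seq_along(bl),
    n = vapply(bl, length, 0L),
    accuracy = vapply(bl, function(i) mean(oc$correct[i]), 0))
  structure(list(n_trials = nrow(oc), n_correct = n_correct,
                 n_nodecision = n_nodec, accuracy = acc,
                 p_value = ct$p_value, p_value_chisq = ct$p_value_chisq,
                 significant = ct$significant,
                 itr_bits_per_min = tryCatch(itr_with_pauses(log),
                                             error = function(e) NA_real_),
                 blocks = blocks),
            class = "bci_session_result")
}

#' @export
print.bci_session_result <- function(x, ...) {
  cat(sprintf("<bci_session_result> %d trials (%d noDecision): accuracy %.1f%%, p = %.3g%s, ITR %.2f bits/min\n",
              x$n_trials, x$n_nodecision, 100 * x$accuracy, x$p_value,
              if (x$significant) " *" else "", x$itr_bits_per_min))
  invisible(x)
}

#' Exact binomial chance-level test
#'
#' One-sided exact test of the observed number of correct binary decisions
#' against the 50% chance level: `P(X >= n_correct | n_total, p = 0.5)`.
#' A Pearson chi-squared test (1 df) against the same null is reported as a
#' cross-check; the binomial is exact at session-sized trial counts.
#'
#' @param n_correct,n_total counts, `0 <= n_correct <= n_total`.
#' @param alpha significance level for the flag (default 0.05).
#' @return List `p_value` (exact binomial), `p_value_chisq`, `significant`.
#' @examples
#' chance_test(15, 20)$p_value   # 0.0207
#' @export
chance_test <- function(n_correct, n_total, alpha = 0.05) {
  stopifnot(n_total >= 1)
  if (n_correct > n_total) stop("n_correct exceeds n_total")
  p <- stats::pbinom(n_correct - 1, n_total, 0.5, lower.tail = FALSE)
  chi <- stats::chisq.test(c(n_correct, n_total - n_correct),
                           p = c(0.5, 0.5), correct = FALSE)
  list(p_value = p, p_value_chisq = unname(chi$p.value),
       significant = p < alpha)
}

#' Wolpaw bits per selection
#'
#' The per-selection information content of an N-class selection at accuracy
#' P: `log2 N + P log2 P + (1 - P) log2((1 - P)/(N - 1))`, with
#' `0 * log 0 = 0`. For two classes this is 1 bit at P = 1 and 0 bits at
#' chance (P = 0.5).
#'
#' @param P accuracy in `[0, 1]`.
#' @param N number of classes (default 2).
#' @return Bits per selection.
#' @examples
#' wolpaw_bits(1)     # 1
#' wolpaw_bits(0.9)   # 0.531
#' @export
wolpaw_bits <- function(P, N = 2) {
  stopifnot(all(P >= 0), all(P <= 1), N >= 2)
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  log2(N) + xlx(P) + ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
}

#' Pause-aware information transfer rate
#'
#' Wolpaw bits per selection (computed over decided trials' accuracy) times
#' the number of decided trials, divided by the total elapsed session time
#' -- trials, noDecision trials and all pauses included. Undecided time thus
#' reduces the rate even though it contributes no selections, which is how
#' the communication cost of a conservative threshold shows up.
#'
#' @param log a `bci_session` with a populated session clock, or a list with
#'   `n_decided`, `n_correct`, `elapsed_s`.
#' @param N number of classes (default 2).
#' @return Bits per minute.
#' @export
itr_with_pauses <- function(log, N = 2) {
  if (inherits(log, "bci_session")) {
    oc <- log$outcomes
    elapsed <- max(oc$t_end) - min(oc$t_start) + log$pauses_extra
    decided <- oc$decision != "noDecision" & !is.na(oc$correct)
    n_dec <- sum(decided)
    n_cor <- sum(oc$correct[decided])
  } else {
    elapsed <- log$elapsed_s; n_dec <- log$n_decided; n_cor <- log$n_correct
  }
  if (elapsed <= 0) stop("zero elapsed time")
  if (n_dec == 0) return(0)
  wolpaw_bits(n_cor / n_dec, N) * n_dec / (elapsed / 60)
}

#' Leakage-free cross-validated accuracy
#'
#' K-fold cross-validation of the oscillatory pipeline: CSP filters and the
#' shrinkage LDA are fitted inside each training fold only, and accuracy is
#' assessed on the held-out fold -- fitting the spatial filters outside the
#' folds would leak label information and inflate accuracy. Default 5 folds.
#'
#' @param ep a band-pass-filtered [epochset()] with labels.
#' @param interval ms window for covariance/feature extraction (default full
#'   epoch).
#' @param k folds (default 5); reduced with a warning if a class has fewer
#'   trials than folds.
#' @param n_select CSP components (default 6).
#' @param seed RNG seed for the fold assignment.
#' @return List `accuracy` (mean over folds), `fold_accuracy`, `sd`, `k`.
#' @export
crossval_accuracy <- function(ep, interval = NULL, k = 5, n_select = 6,
                              seed = 1) {
  stopifnot(inherits(ep, "bci_epochs"))
  labs <- ep$labels
  ok <- which(!is.na(labs))
  n_min <- min(table(labs[ok]))
  k <- as.integer(k)
  if (n_min < k) {
    k <- max(2L, as.integer(n_min))
    warning("too few trials per class; reducing to ", k, " folds")
  }
  set.seed(seed)
  folds <- integer(length(labs))
  for (cl in 1:2) {     # stratified assignment
    i <- which(labs == cl)
    folds[i] <- sample(rep(seq_len(k), length.out = length(i)))
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- which(folds != f & !is.na(labs))
    te <- which(folds == f & !is.na(labs))
    sub <- ep; sub$data <- ep$data[tr, , , drop = FALSE]
    sub$labels <- labs[tr]
    bank <- fit_csp(sub, interval, n_select)
    Xtr <- csp_logvar(sub, bank, interval)
    m <- train_shrinkage_lda(Xtr, labs[tr])
    tes <- ep; tes$data <- ep$data[te, , , drop = FALSE]
    tes$labels <- labs[te]
    Xte <- csp_logvar(tes, bank, interval)
    pred <- ifelse(lda_score(m, Xte) > 0, 2L, 1L)
    mean(pred == labs[te])
  }, 0)
  list(accuracy = mean(acc), fold_accuracy = acc, sd = stats::sd(acc), k = k)
}

#' Welch-averaged power spectral density
#'
#' Hann-windowed, 50%-overlapping segment-averaged periodogram, normalized
#' so that the integral of the density over frequency equals the signal
#' variance (Parseval).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default `min(256, length(x))`).
#' @return List `freq` (Hz), `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(256L, length(x))) {
  n <- length(x)
  if (n < nperseg) stop("signal shorter than one segment")
  step <- nperseg %/% 2L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  scale <- fs * sum(win^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * win
    p <- abs(stats::fft(seg))^2 / scale
    acc <- acc + p
  }
  p <- acc / length(starts)
  nf <- nperseg %/% 2L + 1L
  psd <- p[seq_len(nf)]
  if (nperseg %% 2L == 0L) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  else psd[2:nf] <- 2 * psd[2:nf]
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

#' Spectral screening of a recording
#'
#' The standard pre-study sanity check: per-channel Welch spectra under
#' eyes-open and eyes-closed conditions, plus the scalar 8-12 Hz alpha-band
#' power per channel and condition. A visible occipital/parietal alpha
#' increase with closed eyes indicates usable idle rhythms.
#'
#' @param rec a [recording()].
#' @param segments data.frame with columns `start`, `end` (0-based sample
#'   indices, half-open) and `condition` (e.g. `"eyes-open"`,
#'   `"eyes-closed"`).
#' @param alpha a [band()] for the topography scalar (default 8-12 Hz).
#' @param nperseg Welch segment length (default 256 samples).
#' @return List per condition: `freq`, `psd` (channels x freqs),
#'   `alpha_power` (per channel).
#' @export
spectral_screening <- function(rec, segments, alpha = band(8, 12, "alpha"),
                               nperseg = 256L) {
  stopifnot(inherits(rec, "bci_recording"))
  out <- list()
  for (cond in unique(segments$condition)) {
    seg <- segments[segments$condition == cond, , drop = FALSE]
    pieces <- lapply(seq_len(nrow(seg)), function(i)
      rec$signal[, (seg$start[i] + 1L):seg$end[i], drop = FALSE])
    x <- do.call(cbind, pieces)
    if (ncol(x) < nperseg)
      stop("condition '", cond, "' shorter than one Welch window")
    psd <- NULL
    for (ch in seq_len(nrow(x))) {
      w <- welch_psd(x[ch, ], rec$fs, nperseg)
      if (is.null(psd)) psd <- matrix(0, nrow(x), length(w$freq))
      psd[ch, ] <- w$psd
      freq <- w$freq
    }
    sel <- freq >= alpha$lo & freq <= alpha$hi
    df <- freq[2] - freq[1]
    out[[cond]] <- list(freq = freq, psd = psd,
                        alpha_power = rowSums(psd[, sel, drop = FALSE]) * df)
  }
  out
}
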