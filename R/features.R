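#' Slow-potential (LRP) mean-amplitude features
#'
#' For the slow-potential branch: per trial, the mean amplitude over a
#' class-discriminative time interval, taken from each channel. The epochs
#' should be 0.2-4 Hz band-pass filtered and baseline-corrected first, so a
#' lateralized readiness potential shows up as a slow deflection whose mean
#' amplitude differs between classes with opposite sign over the two motor
#' cortices.
#'
#' @param ep a filtered, baseline-corrected [epochset()].
#' @param interval `c(t0, t1)` ms window, half-open.
#' @return Matrix trials x channels.
#' @export
lrp_features <- function(ep, interval) {
  stopifnot(inherits(ep, "bci_epochs"))
  idx <- interval_index(ep, interval)
  t(apply(ep$data[, , idx, drop = FALSE], 1, function(x)
    rowMeans(matrix(x, nrow = dim(ep$data)[2]))))
}

#' Signed, scaled AUC discriminability map
#'
#' For each feature cell, computes `2 * (AUC - 0.5)` where AUC is the
#' rank-sum (Mann-Whitney) area under the ROC curve for class-2 versus
#' class-1 values. The result lies in `[-1, 1]`: 0 means the class
#' distributions are indistinguishable, +1 that every class-2 value exceeds
#' every class-1 value, -1 the reverse. Ties count one half.
#'
#' @param x either a [epochset()] (returns a channels x samples map) or a
#'   trials x features matrix.
#' @param labels per-observation class in `{1, 2}`; taken from `x$labels`
#'   when `x` is an epoch set.
#' @return Numeric matrix (channels x samples) or vector (per feature) of
#'   signed scaled AUC values.
#' @export
ssauc_map <- function(x, labels = NULL) {
  if (inherits(x, "bci_epochs")) {
    labels <- labels %||% x$labels
    d <- dim(x$data)
    out <- matrix(0, d[2], d[3])
    for (ch in seq_len(d[2]))
      for (s in seq_len(d[3]))
        out[ch, s] <- ssauc(x$data[, ch, s], labels)
    rownames(out) <- x$channel_labels
    return(out)
  }
  x <- as.matrix(x)
  apply(x, 2, ssauc, labels = labels)
}

ssauc <- function(values, labels) {
  v1 <- values[labels == 1]; v2 <- values[labels == 2]
  if (length(v1) < 1 || length(v2) < 1)
    stop("both classes need at least one observation")
  # rank-sum AUC for class 2 vs class 1; ties count one half
  r <- rank(c(v1, v2))
  r2 <- sum(r[(length(v1) + 1):(length(v1) + length(v2))])
  auc <- (r2 - length(v2) * (length(v2) + 1) / 2) / (length(v1) * length(v2))
  2 * (auc - 0.5)
}
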