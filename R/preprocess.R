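#' Anti-alias low-pass filter and down-sample a recording
#'
#' Standard front-end step: low-pass filter (zero-phase Butterworth, order 8)
#' below the new Nyquist frequency, then decimate to `fs_out`. Marker sample
#' indices are rescaled by `fs_out / fs` and rounded down; at typical trial
#' lengths of several seconds the sub-sample cue latency is irrelevant.
#'
#' @param rec a [recording()].
#' @param cutoff_hz anti-alias cutoff in Hz (default 45).
#' @param fs_out target sampling rate in Hz (default 100); `rec$fs / fs_out`
#'   must be a positive integer.
#' @return A [recording()] at `fs_out`.
#' @export
lowpass_downsample <- function(rec, cutoff_hz = 45, fs_out = 100) {
  stopifnot(inherits(rec, "bci_recording"))
  if (cutoff_hz >= fs_out / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below the output Nyquist (",
         fs_out / 2, " Hz)")
  ratio <- rec$fs / fs_out
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("fs_out must divide rec$fs (got ratio ", ratio, ")")
  ratio <- as.integer(round(ratio))
  sos <- butter_sos(8, hi = cutoff_hz, fs = rec$fs, type = "lowpass")
  sig <- rec$signal
  if (ratio > 1L) {
    for (ch in seq_len(nrow(sig))) sig[ch, ] <- sos_filtfilt(sos, sig[ch, ])
    keep <- seq(1L, ncol(sig), by = ratio)
    sig <- sig[, keep, drop = FALSE]
  }
  markers <- rec$markers
  markers$sample <- as.integer(floor(markers$sample / ratio))
  markers <- markers[markers$sample < ncol(sig), , drop = FALSE]
  recording(sig, fs = fs_out, channel_labels = rec$channel_labels,
            markers = markers)
}

#' Band-pass (or low-pass) filter a recording or epoch set
#'
#' Applies the filter described by `spec` channel-wise. Causal mode is the
#' streaming path used for online feedback (output at time t depends only on
#' samples up to t); zero-phase mode is for offline analyses.
#'
#' @param x a [recording()] or [epochset()].
#' @param spec a [filter_spec()].
#' @return Object of the same class and shape as `x`.
#' @export
bandpass <- function(x, spec) {
  stopifnot(inherits(spec, "bci_filter_spec"))
  fs <- x$fs
  sos <- if (spec$kind == "bandpass")
    butter_sos(spec$order, spec$band$lo, spec$band$hi, fs, "bandpass")
  else
    butter_sos(spec$order, hi = if (inherits(spec$band, "bci_band"))
      spec$band$hi else spec$band, fs = fs, type = "lowpass")
  if (max(abs(sos_poles(sos))) >= 1)
    stop("numerical error: unstable filter design (pole outside unit circle)")
  ff <- if (spec$mode == "zero-phase") sos_filtfilt else sos_filter
  if (inherits(x, "bci_recording")) {
    sig <- x$signal
    for (ch in seq_len(nrow(sig))) sig[ch, ] <- ff(sos, sig[ch, ])
    recording(sig, fs, x$channel_labels, x$markers)
  } else if (inherits(x, "bci_epochs")) {
    d <- x$data
    for (tr in seq_len(dim(d)[1]))
      for (ch in seq_len(dim(d)[2]))
        d[tr, ch, ] <- ff(sos, d[tr, ch, ])
    out <- x; out$data <- d
    out
  } else stop("x must be a bci_recording or bci_epochs")
}

sos_poles <- function(sos) {
  # roots of a0 z^2 + a1 z + a2 per section
  unlist(lapply(seq_len(nrow(sos)), function(s)
    polyroot(rev(sos[s, 4:6]))))
}

#' Channel-wise baseline correction
#'
#' Subtracts, per trial and channel, the mean amplitude over a pre-onset
#' reference interval (default the 300 ms before trial onset). Required
#' before slow-potential (LRP) feature extraction.
#'
#' @param ep a [epochset()] whose `times` cover `interval`.
#' @param interval `c(t0, t1)` in ms, half-open `[t0, t1)`.
#' @return Baseline-corrected [epochset()].
#' @export
baseline_correct <- function(ep, interval = c(-300, 0)) {
  stopifnot(inherits(ep, "bci_epochs"))
  idx <- which(ep$times >= interval[1] & ep$times < interval[2])
  if (length(idx) == 0)
    stop("baseline interval [", interval[1], ", ", interval[2],
         ") ms not covered by epoch times")
  d <- ep$data
  bl <- apply(d[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- d - array(rep(bl, dim(d)[3]), dim = dim(d))
  ep
}
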