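#' Design a Butterworth filter as second-order sections
#'
#' Designs the analog Butterworth prototype in zero-pole-gain form, frequency
#' warps it, applies the bilinear transform and pairs conjugate roots into
#' biquads. Second-order sections keep an order-5 band-pass stable even with a
#' 0.2 Hz lower edge, where the expanded transfer-function polynomial is
#' numerically unusable.
#'
#' @param order prototype order (the band-pass has `2*order` poles).
#' @param lo,hi corner frequencies in Hz. Low-pass uses `hi` only, high-pass
#'   `lo` only, band-pass both.
#' @param fs sampling rate in Hz.
#' @param type `"lowpass"`, `"highpass"` or `"bandpass"`.
#' @return Matrix `n_sections x 6`, columns `b0 b1 b2 a0 a1 a2` (`a0 = 1`).
#' @export
butter_sos <- function(order, lo = NULL, hi = NULL, fs,
                       type = c("bandpass", "lowpass", "highpass")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fs > 0)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  # analog Butterworth prototype: poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  if (order %% 2 == 1) p[(order + 1) / 2] <- -1 + 0i  # force the real pole exact
  z <- complex(0)
  gain <- 1
  if (type == "lowpass") {
    if (is.null(hi) || hi <= 0 || hi >= fs / 2) stop("cutoff must lie in (0, fs/2)")
    wc <- warp(hi)
    p <- p * wc; gain <- wc^order
  } else if (type == "highpass") {
    if (is.null(lo) || lo <= 0 || lo >= fs / 2) stop("cutoff must lie in (0, fs/2)")
    wc <- warp(lo)
    p <- wc / p
    z <- rep(0 + 0i, order)
    gain <- 1  # equal zero/pole count: unity gain at infinite frequency
  } else {
    if (is.null(lo) || is.null(hi) || !(0 < lo && lo < hi && hi < fs / 2))
      stop("band edges must satisfy 0 < lo < hi < fs/2")
    wlo <- warp(lo); whi <- warp(hi)
    w0 <- sqrt(wlo * whi); bw <- whi - wlo
    ps <- p * bw / 2
    p <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
    z <- rep(0 + 0i, order)
    gain <- bw^order
  }
  # bilinear transform s -> z
  fs2 <- 2 * fs
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))  # zeros at Nyquist fill the degree
  sos_from_zpk(zd, pd, gain)
}

# pair conjugate roots into biquads; gain applied to the first section
sos_from_zpk <- function(z, p, k) {
  pair_up <- function(r) {
    r <- r[order(abs(Im(r)) < 1e-10, Re(r))]  # complex pairs first
    used <- rep(FALSE, length(r))
    pairs <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) > 1e-10) {
        j <- which(!used & abs(r - Conj(r[i])) ==
                     min(abs(r[!used] - Conj(r[i]))))[1]
        used[j] <- TRUE
        pairs[[length(pairs) + 1]] <- c(r[i], r[j])
      } else {
        j <- which(!used & abs(Im(r)) <= 1e-10)[1]
        if (is.na(j)) pairs[[length(pairs) + 1]] <- r[i]
        else { used[j] <- TRUE; pairs[[length(pairs) + 1]] <- c(r[i], r[j]) }
      }
    }
    pairs
  }
  np <- length(p)
  nsec <- ceiling(np / 2)
  zp <- pair_up(z); pp <- pair_up(p)
  sos <- matrix(0, nsec, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (s in seq_len(nsec)) {
    zs <- if (s <= length(zp)) zp[[s]] else complex(0)
    ps <- pp[[s]]
    bp <- Re(poly_from_roots(zs))
    ap <- Re(poly_from_roots(ps))
    sos[s, 1:3] <- c(bp, rep(0, 3 - length(bp)))
    sos[s, 4:6] <- c(ap, rep(0, 3 - length(ap)))
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Causal (streaming-compatible) SOS filtering
#'
#' Direct-form filtering through each biquad in turn with zero initial
#' conditions: the output at sample t depends only on samples <= t, as
#' required for online feedback.
#'
#' @param sos matrix from [butter_sos()].
#' @param x numeric vector.
#' @return Filtered vector, same length.
#' @export
sos_filter <- function(sos, x) {
  n <- length(x)
  y <- as.numeric(x)
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 5:6]
    x1 <- c(0, y[-n]); x2 <- c(0, 0, y[seq_len(max(0, n - 2))])
    v <- b[1] * y + b[2] * x1 + b[3] * x2
    y <- as.numeric(stats::filter(v, -a, method = "recursive"))
  }
  y
}

#' Zero-phase SOS filtering (forward-backward)
#'
#' Filters forward then backward, cancelling the group delay; usable offline
#' only. Edge transients are reduced with odd-symmetric signal extension.
#'
#' @inheritParams sos_filter
#' @param padlen extension length in samples (default `18 * n_sections`,
#'   clipped to `length(x) - 1`).
#' @return Filtered vector, same length.
#' @export
sos_filtfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 18L * nrow(sos)
  padlen <- min(padlen, n - 1L)
  if (padlen > 0) {
    front <- 2 * x[1] - x[seq(padlen + 1, 2)]
    back <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xe <- c(front, x, back)
  } else xe <- x
  y <- sos_filter(sos, xe)
  y <- rev(sos_filter(sos, rev(y)))
  y[seq(padlen + 1, padlen + n)]
}

#' Complex frequency response of an SOS filter
#'
#' @param sos matrix from [butter_sos()].
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return Complex vector `H(f)`; `abs()` gives the gain.
#' @export
sos_freq_response <- function(sos, f, fs) {
  e1 <- exp(-2i * pi * f / fs)
  e2 <- e1^2
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos)))
    h <- h * (sos[s, 1] + sos[s, 2] * e1 + sos[s, 3] * e2) /
      (sos[s, 4] + sos[s, 5] * e1 + sos[s, 6] * e2)
  h
}

#' Specify a filtering step
#'
#' Serializable description of one filter: kind, order, band and phase mode.
#' `mode = "causal"` is mandatory inside the online engine; `"zero-phase"` is
#' allowed for offline analyses.
#'
#' @param kind `"lowpass"` or `"bandpass"`.
#' @param order Butterworth prototype order (default 5, the package-wide
#'   band-pass order).
#' @param band a [band()] for band-pass, or a single cutoff in Hz for low-pass.
#' @param mode `"causal"` or `"zero-phase"`.
#' @return A `bci_filter_spec` list.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), order = 5,
                        band, mode = c("causal", "zero-phase")) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  stopifnot(order >= 1)
  if (kind == "bandpass" && !inherits(band, "bci_band"))
    stop("bandpass needs a band() object")
  structure(list(kind = kind, order = order, band = band, mode = mode),
            class = "bci_filter_spec")
}
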