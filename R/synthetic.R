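#' Configuration for the ground-truth EEG generator
#'
#' Describes a simulated two-class motor-imagery session: 1/f background
#' noise on every channel, two lateralized band-limited sources mixed in
#' through smooth scalp topographies centered near C3 and C4, class-dependent
#' event-related desynchronization (ERD) of the corresponding source during
#' its trials, a post-trial beta-style rebound, and a slow lateralized
#' readiness-potential (LRP) ramp over the contralateral motor channel.
#' Session-to-session nonstationarity is modeled as a slow per-trial rotation
#' of the source mixing columns ("drift").
#'
#' Defaults follow the recording setup the pipeline targets: 16 channels at
#' 100 Hz, 5 s trials; ERD in the 8-12 Hz band with a 50% power drop;
#' rebound gain 2 for 1 s starting 500 ms after trial end; 5 microvolt LRP
#' ramp; source-to-background SNR 1.
#'
#' @param n_channels number of EEG channels (default 16).
#' @param fs sampling rate in Hz (default 100).
#' @param n_trials trials per class (default 20).
#' @param trial_len trial length in seconds (default 5).
#' @param pause_len inter-trial pause in seconds (default 3).
#' @param erd_band a [band()]: the oscillatory band carrying the ERD.
#' @param erd_depth fractional variance reduction in `[0, 1]` of the
#'   class-specific source during its trials.
#' @param rebound_gain post-trial variance multiplier (>= 1) applied for 1 s
#'   starting 500 ms after trial end.
#' @param lrp_amplitude LRP ramp depth in microvolts (negative deflection).
#' @param snr source-to-background amplitude variance ratio.
#' @param drift_rate per-trial rotation of the mixing columns, degrees.
#' @param seed RNG seed; mandatory for reproducibility.
#' @return A `bci_synth_config` list.
#' @export
synthetic_config <- function(n_channels = 16, fs = 100, n_trials = 20,
                             trial_len = 5, pause_len = 3,
                             erd_band = band(8, 12, "alpha"),
                             erd_depth = 0.5, rebound_gain = 2,
                             lrp_amplitude = 5, snr = 1,
                             drift_rate = 0, seed = 1) {
  stopifnot(erd_depth >= 0, erd_depth <= 1, rebound_gain >= 1, snr >= 0,
            n_channels >= 4, fs > 0, n_trials >= 1)
  if (erd_band$hi >= fs / 2) stop("erd_band upper edge must be below Nyquist")
  structure(as.list(environment()), class = "bci_synth_config")
}

#' Generate a synthetic motor-imagery recording with ground truth
#'
#' Builds a continuous recording of `2 * n_trials` cued trials (classes
#' interleaved in randomized order) according to `cfg`. The returned ground
#' truth carries the planted mixing columns, trial schedule and labels, and
#' the nominal effect sizes, so tests can check parameter recovery instead
#' of eyeballing.
#'
#' @param cfg a [synthetic_config()].
#' @param labels optional explicit per-trial label sequence (overrides the
#'   shuffled default; values in `{1, 2}`).
#' @return List with `recording` (a [recording()]; markers `class1`/`class2`
#'   at trial onsets and `trial_end` at offsets) and `truth` (list: `mixing`
#'   channels x 2, `labels`, `onsets` in samples, `cfg`).
#' @export
generate_recording <- function(cfg, labels = NULL) {
  stopifnot(inherits(cfg, "bci_synth_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  n_tr <- if (is.null(labels)) 2L * cfg$n_trials else length(labels)
  if (is.null(labels))
    labels <- sample(rep(1:2, cfg$n_trials))
  trial_s <- round(cfg$trial_len * fs)
  pause_s <- round(cfg$pause_len * fs)
  lead <- pause_s  # settle-in time before the first trial
  n <- lead + n_tr * (trial_s + pause_s)
  nch <- cfg$n_channels

  # 1/f background, unit variance per channel
  bg <- vapply(seq_len(nch), function(i) pink_noise(n), numeric(n))
  # two band-limited sources at unit baseline variance
  sos <- butter_sos(4, cfg$erd_band$lo, cfg$erd_band$hi, fs, "bandpass")
  src <- vapply(1:2, function(i) {
    s <- sos_filter(sos, stats::rnorm(n))
    s / stats::sd(s)
  }, numeric(n))

  mix <- scalp_mixing(nch)   # channels x 2, bumps near C3 / C4
  onsets <- lead + (seq_len(n_tr) - 1L) * (trial_s + pause_s)

  # per-sample amplitude envelope per source: ERD during own-class trials,
  # rebound for 1 s starting 500 ms after trial end
  env <- matrix(1, n, 2)
  reb0 <- round(0.5 * fs); reb_len <- round(1.0 * fs)
  for (k in seq_len(n_tr)) {
    t0 <- onsets[k] + 1L; t1 <- onsets[k] + trial_s
    cl <- labels[k]
    env[t0:t1, cl] <- sqrt(1 - cfg$erd_depth)
    r0 <- min(t1 + reb0 + 1L, n); r1 <- min(t1 + reb0 + reb_len, n)
    env[r0:r1, cl] <- sqrt(cfg$rebound_gain)
  }

  amp <- sqrt(cfg$snr)
  sig <- t(bg)
  if (cfg$drift_rate == 0) {
    sig <- sig + amp * (mix %*% t(src * env))
  } else {
    # rotate the two mixing columns in their own plane, drift_rate deg/trial
    trial_of <- findInterval(seq_len(n) - 1L, onsets)
    for (k in 0:n_tr) {
      span <- which(trial_of == k)
      if (!length(span)) next
      mk <- rotate_columns(mix, k * cfg$drift_rate * pi / 180)
      sig[, span] <- sig[, span] +
        amp * (mk %*% t(src[span, , drop = FALSE] * env[span, , drop = FALSE]))
    }
  }

  # slow lateralized potential: class 1 over the C3-like channel, class 2
  # over C4. Planted as a transient half-sine deflection of ~1.5 s starting
  # 2 s after cue onset: readiness potentials are transient, and a
  # full-trial DC ramp would fall below the 0.2 Hz high-pass edge of the
  # slow branch and vanish by construction.
  lrp_ch <- c(which.max(mix[, 1]), which.max(mix[, 2]))
  bump_len <- min(trial_s, round(1.5 * fs))
  bump_off <- min(trial_s - bump_len, round(2.0 * fs))
  bump <- -cfg$lrp_amplitude * sin(pi * seq(0, 1, length.out = bump_len))
  for (k in seq_len(n_tr)) {
    span <- (onsets[k] + bump_off + 1L):(onsets[k] + bump_off + bump_len)
    sig[lrp_ch[labels[k]], span] <- sig[lrp_ch[labels[k]], span] + bump
  }

  markers <- data.frame(
    sample = as.integer(c(onsets, onsets + trial_s)),
    label = c(paste0("class", labels), rep("trial_end", n_tr)))
  markers <- markers[order(markers$sample), ]
  rec <- recording(sig, fs,
                   channel_labels = montage_labels(nch), markers = markers)
  list(recording = rec,
       truth = list(mixing = mix, labels = labels, onsets = onsets,
                    lrp_channels = lrp_ch, cfg = cfg))
}

# spectrally shaped white noise with 1/f amplitude profile, unit variance
pink_noise <- function(n) {
  nf <- 2^ceiling(log2(n))
  spec <- stats::fft(stats::rnorm(nf))
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)          # symmetric profile keeps the signal real
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# smooth Gaussian bumps over a 1-D channel axis, centered near the C3 and C4
# positions of a left-to-right 16-channel motor montage
scalp_mixing <- function(nch) {
  pos <- seq(0, 1, length.out = nch)
  c3 <- 0.3; c4 <- 0.7; width <- 0.15
  mix <- cbind(exp(-(pos - c3)^2 / (2 * width^2)),
               exp(-(pos - c4)^2 / (2 * width^2)))
  sweep(mix, 2, sqrt(colSums(mix^2)), "/")
}

rotate_columns <- function(mix, angle) {
  # rotation within the span of the two columns
  q <- qr.Q(qr(mix))
  coords <- crossprod(q, mix)
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  q %*% (rot %*% coords)
}

montage_labels <- function(nch) {
  std <- c("F3", "Fz", "F4", "FC3", "FCz", "FC4", "C5", "C3",
           "Cz", "C4", "C6", "CP3", "CPz", "CP4", "P3", "P4")
  if (nch <= length(std)) std[seq_len(nch)]
  else c(std, paste0("ch", seq_len(nch - length(std))))
}

#' Synthetic stream for a scripted FreeMode user
#'
#' Produces a recording whose per-trial class follows a scripted intent
#' sequence, at a configurable `controllability`: the probability that a
#' trial actually expresses the intended class's signature (below 1 the
#' expressed class is re-drawn uniformly, modeling unreliable control). The
#' cue markers are question marks -- FreeMode trials are unlabeled -- and the
#' true intents are returned separately.
#'
#' @param intents integer vector of intended classes in `{1, 2}`.
#' @param cfg a [synthetic_config()].
#' @param controllability probability in `[0, 1]` that the intended
#'   signature is expressed (default 1).
#' @return List `recording` (markers: `question` at onsets, `trial_end`),
#'   `intents`, `expressed` (classes actually planted), `truth`.
#' @export
scripted_user <- function(intents, cfg, controllability = 1) {
  stopifnot(all(intents %in% 1:2), controllability >= 0, controllability <= 1)
  set.seed(cfg$seed)
  expressed <- ifelse(stats::runif(length(intents)) < controllability,
                      intents, sample(1:2, length(intents), replace = TRUE))
  cfg$seed <- cfg$seed + 1L   # the generator reseeds; keep draws distinct
  gen <- generate_recording(cfg, labels = expressed)
  rec <- gen$recording
  rec$markers$label[rec$markers$label %in% c("class1", "class2")] <- "question"
  list(recording = rec, intents = intents, expressed = expressed,
       truth = gen$truth)
}
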