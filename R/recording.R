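#' Construct a multichannel EEG recording
#'
#' A `bci_recording` holds a continuous multichannel EEG signal in microvolts
#' together with its sampling rate, channel montage labels and a marker table
#' (cue events). It is the raw material every downstream stage consumes.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of montage names (e.g. "C3", "Cz",
#'   "C4"); length must equal `nrow(signal)`.
#' @param markers data.frame with columns `sample` (0-based integer sample
#'   index) and `label` (cue identifier). May have zero rows.
#'
#' @return An object of class `bci_recording` with fields `signal`, `fs`,
#'   `channel_labels`, `markers`.
#' @seealso [read_recording()], [write_recording()], [epoch()]
#' @export
recording <- function(signal, fs, channel_labels = NULL, markers = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal))
    stop("channel_labels length (", length(channel_labels),
         ") must equal the channel dimension of signal (", nrow(signal), ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(markers))
    markers <- data.frame(sample = integer(0), label = character(0))
  markers <- as.data.frame(markers)
  if (!all(c("sample", "label") %in% names(markers)))
    stop("markers must have columns 'sample' and 'label'")
  markers$sample <- as.integer(markers$sample)
  markers$label <- as.character(markers$label)
  n <- ncol(signal)
  if (nrow(markers) && (any(markers$sample < 0L) || any(markers$sample >= n)))
    stop("marker sample indices must lie in [0, n_samples)")
  structure(
    list(signal = signal, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels),
         markers = markers[, c("sample", "label")]),
    class = "bci_recording")
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, nrow(x$markers)))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  if (nrow(x$markers)) {
    tab <- table(x$markers$label)
    cat("  markers: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Marker label vocabulary
#'
#' The cue vocabulary used throughout the package: `"class1"` and `"class2"`
#' are the two motor-imagery cues, `"question"` is the FreeMode cue (class
#' unknown), `"trial_end"` closes a trial.
#'
#' @return Named character vector of the four labels.
#' @export
marker_vocabulary <- function() {
  c(class1 = "class1", class2 = "class2",
    question = "question", trial_end = "trial_end")
}

#' Define a frequency band
#'
#' @param lo,hi band edges in Hz, `0 <= lo < hi`.
#' @param name optional label, e.g. `"alpha"`.
#' @return A `bci_band` list with `lo`, `hi`, `name`.
#' @examples
#' band(8, 12, "alpha")
#' @export
band <- function(lo, hi, name = NULL) {
  if (!(lo >= 0 && lo < hi)) stop("need 0 <= lo < hi")
  structure(list(lo = lo, hi = hi,
                 name = if (is.null(name)) sprintf("%g-%g Hz", lo, hi) else name),
            class = "bci_band")
}

#' Construct an epoch set
#'
#' Usually produced by [epoch()]; the constructor validates invariants.
#'
#' @param data numeric array, trials x channels x samples, microvolts.
#' @param times per-sample latency in ms relative to trial onset; strictly
#'   increasing, uniform at 1000/fs spacing.
#' @param labels per-trial class, integers in `{1, 2}` or `NA` for unknown.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel montage names.
#' @return An object of class `bci_epochs`.
#' @export
epochset <- function(data, times, labels, fs, channel_labels = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be trials x channels x samples")
  if (length(times) != dim(data)[3])
    stop("times length must equal sample dimension")
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - 1000 / fs)) > 1e-6)
      stop("times must be strictly increasing with uniform spacing 1000/fs ms")
  }
  if (length(labels) != dim(data)[1])
    stop("labels length must equal trial count")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(dim(data)[2]))
  structure(list(data = data, times = as.numeric(times),
                 labels = as.integer(labels), fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels)),
            class = "bci_epochs")
}

#' @export
print.bci_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bci_epochs> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g] ms\n",
              d[1], d[2], d[3], x$fs, x$times[1],
              x$times[length(x$times)] + 1000 / x$fs))
  lab <- table(factor(x$labels, levels = c(1, 2)), useNA = "ifany")
  cat(sprintf("  labels: class1=%d class2=%d unknown=%d\n",
              lab[["1"]], lab[["2"]], sum(is.na(x$labels))))
  invisible(x)
}

#' Cut trials out of a continuous recording
#'
#' Extracts one epoch per marker whose label is in `cue_labels`, using a
#' half-open window `[t0, t1)` in milliseconds relative to the marker sample
#' (0-based; the onset sample is included when `t0 = 0`). Markers whose window
#' would exceed the recording bounds are excluded -- not zero-padded, which
#' would corrupt downstream covariance estimates -- and reported via the
#' `excluded` attribute and a warning.
#'
#' @param rec a [recording()].
#' @param cue_labels character vector of marker labels to epoch around;
#'   `"class1"`/`"class2"` map to labels 1/2, anything else to `NA` (unknown).
#' @param window numeric length-2, `c(t0, t1)` in ms.
#' @return A [epochset()] with one trial per retained marker, in marker order.
#'   Attribute `excluded`: integer indices (into the selected markers) that
#'   were dropped.
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), fs = 100,
#'                  markers = data.frame(sample = 50, label = "class1"))
#' ep <- epoch(rec, c("class1", "class2"), c(0, 300))
#' dim(ep$data)  # 1 x 2 x 30
#' @export
epoch <- function(rec, cue_labels = c("class1", "class2"),
                  window = c(0, 5000)) {
  stopifnot(inherits(rec, "bci_recording"), length(window) == 2,
            window[1] < window[2])
  sel <- rec$markers[rec$markers$label %in% cue_labels, , drop = FALSE]
  fs <- rec$fs
  n <- ncol(rec$signal)
  # half-open sample window [i0, i1) relative to the marker sample
  i0 <- as.integer(round(window[1] * fs / 1000))
  i1 <- as.integer(round(window[2] * fs / 1000))
  nsamp <- i1 - i0
  if (nsamp < 1) stop("window shorter than one sample at fs = ", fs)
  starts <- sel$sample + i0
  ok <- starts >= 0L & (starts + nsamp) <= n
  if (any(!ok))
    warning(sum(!ok), " marker(s) excluded: epoch window exceeds recording bounds")
  kept <- sel[ok, , drop = FALSE]
  data <- array(0, dim = c(nrow(kept), nrow(rec$signal), nsamp))
  for (k in seq_len(nrow(kept))) {
    s0 <- kept$sample[k] + i0
    data[k, , ] <- rec$signal[, (s0 + 1L):(s0 + nsamp), drop = FALSE]
  }
  labels <- ifelse(kept$label == "class1", 1L,
                   ifelse(kept$label == "class2", 2L, NA_integer_))
  times <- (i0 + seq_len(nsamp) - 1L) * 1000 / fs
  ep <- epochset(data, times, labels, fs, rec$channel_labels)
  attr(ep, "excluded") <- which(!ok)
  ep
}

#' Read a recording bundle from disk
#'
#' The on-disk bundle is a directory with `header.json` (fs, channel_labels,
#' dtype, n_samples), `signal.bin` (float32 little-endian, samples-major: all
#' channels of sample 0, then sample 1, ...) and `markers.csv`
#' (columns `sample,label`). A plain CSV matrix (first row channel labels, one
#' row per sample) is accepted for tiny fixtures when `path` is a `.csv` file.
#'
#' @param path directory containing the bundle, or a `.csv` fixture.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  if (grepl("\\.csv$", path) && file.exists(path) && !dir.exists(path)) {
    tab <- utils::read.csv(path, check.names = FALSE)
    return(recording(t(as.matrix(tab)), fs = attr(tab, "fs") %||% 100,
                     channel_labels = names(tab)))
  }
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath)) stop("format error: header.json missing in ", path)
  hdr <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (f in c("fs", "channel_labels", "dtype", "n_samples"))
    if (is.null(hdr[[f]])) stop("format error: header field '", f, "' missing")
  if (!identical(hdr$dtype, "float32"))
    stop("format error: unsupported dtype '", hdr$dtype, "'")
  nch <- length(hdr$channel_labels)
  ns <- as.integer(hdr$n_samples)
  bpath <- file.path(path, "signal.bin")
  expect_bytes <- 4 * nch * ns
  if (!file.exists(bpath) || file.size(bpath) != expect_bytes)
    stop("format error: signal.bin size ",
         if (file.exists(bpath)) file.size(bpath) else "missing",
         " does not match header (expected ", expect_bytes, " bytes)")
  raw <- readBin(bpath, "numeric", n = nch * ns, size = 4, endian = "little")
  sig <- matrix(raw, nrow = nch, ncol = ns)  # samples-major payload
  mpath <- file.path(path, "markers.csv")
  markers <- if (file.exists(mpath))
    utils::read.csv(mpath, colClasses = c("integer", "character"))
  else data.frame(sample = integer(0), label = character(0))
  recording(sig, fs = hdr$fs, channel_labels = hdr$channel_labels,
            markers = markers)
}

#' Write a recording bundle to disk
#'
#' Inverse of [read_recording()]; lossless for float32 payloads.
#'
#' @param rec a [recording()].
#' @param path target directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bci_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(fs = rec$fs, channel_labels = rec$channel_labels,
              dtype = "float32", n_samples = ncol(rec$signal),
              units = "microvolts")
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  writeBin(as.numeric(rec$signal), file.path(path, "signal.bin"),
           size = 4, endian = "little")
  utils::write.csv(rec$markers, file.path(path, "markers.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
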