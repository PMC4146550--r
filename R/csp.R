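#' Fit Common Spatial Patterns
#'
#' Supervised spatial filtering for two-class oscillatory features. Per-trial
#' spatial covariances over `interval` are trace-normalized and averaged
#' within class, giving C1 and C2; the filters solve the generalized
#' eigenproblem of (C1, C1 + C2), so each component's eigenvalue is the
#' fraction of (normalized) variance it captures for class 1 and eigenvalues
#' for the two classes sum to 1 per component. Components from both ends of
#' the spectrum are the discriminative ones.
#'
#' Rank-deficient covariances (few trials, many channels) are regularized by
#' adding `1e-8 * trace * I` with a warning. Pattern sign is normalized so
#' each pattern's largest-magnitude coefficient is positive (the sign of a
#' spatial pattern is arbitrary).
#'
#' @param ep a band-pass-filtered [epochset()] with both classes present
#'   (>= 2 trials each).
#' @param interval `c(t0, t1)` ms window used for covariance estimation;
#'   default the full epoch.
#' @param n_select number of retained components, split evenly between the
#'   two ends (default 6).
#' @return A `bci_csp` object: `filters` (components x channels, all of
#'   them), `patterns` (channels x components, the visualizable scalp
#'   patterns = inverse of the filter matrix), `eigenvalues` (class-1
#'   variance ratios, descending), `selected` (indices retained: half from
#'   each end), `interval`, `channel_labels`.
#' @export
fit_csp <- function(ep, interval = NULL, n_select = 6) {
  stopifnot(inherits(ep, "bci_epochs"))
  idx <- interval_index(ep, interval)
  labs <- ep$labels
  if (length(unique(stats::na.omit(labs))) < 2)
    stop("fit_csp needs trials from both classes")
  covs <- lapply(1:2, function(cl) {
    trials <- which(labs == cl)
    if (length(trials) < 2) stop("need >= 2 trials per class")
    cs <- lapply(trials, function(tr) {
      x <- ep$data[tr, , idx, drop = TRUE]
      c0 <- tcrossprod(x) / length(idx)
      c0 / sum(diag(c0))  # trace-normalize per trial
    })
    Reduce(`+`, cs) / length(cs)
  })
  c1 <- covs[[1]]; cc <- covs[[1]] + covs[[2]]
  nch <- nrow(c1)
  ev <- eigen(cc, symmetric = TRUE)
  if (min(ev$values) < 1e-10 * max(ev$values)) {
    warning("rank-deficient covariance; adding 1e-8 * trace * I")
    reg <- 1e-8 * sum(diag(cc))
    cc <- cc + diag(reg, nch)
    c1 <- c1 + diag(reg / 2, nch)
    ev <- eigen(cc, symmetric = TRUE)
  }
  wh <- ev$vectors %*% diag(1 / sqrt(ev$values), nch)  # whitener of C1+C2
  es <- eigen(crossprod(wh, c1 %*% wh), symmetric = TRUE)
  filters <- t(wh %*% es$vectors)          # components x channels
  eigenvalues <- pmin(pmax(es$values, 0), 1)
  patterns <- solve(filters)               # channels x components
  for (j in seq_len(ncol(patterns))) {
    s <- sign(patterns[which.max(abs(patterns[, j])), j])
    if (s < 0) { patterns[, j] <- -patterns[, j]; filters[j, ] <- -filters[j, ] }
  }
  n_select <- min(n_select, nch - nch %% 2)
  half <- n_select %/% 2
  selected <- c(seq_len(half), seq(nch - half + 1, nch))
  structure(list(filters = filters, patterns = patterns,
                 eigenvalues = eigenvalues, selected = selected,
                 interval = if (is.null(interval))
                   range(ep$times) else interval,
                 channel_labels = ep$channel_labels),
            class = "bci_csp")
}

#' @export
print.bci_csp <- function(x, ...) {
  cat(sprintf("<bci_csp> %d channels, %d components selected; leading eigenvalues: %s\n",
              ncol(x$filters), length(x$selected),
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 3)), collapse = " ")))
  invisible(x)
}

#' Log-variance features after CSP filtering
#'
#' The standard oscillatory band-power feature: per trial, the log of the
#' variance of each selected CSP component over the interval. Variance of a
#' band-limited signal is band power, and the log makes the feature
#' distribution approximately Gaussian for LDA.
#'
#' @param ep a band-pass-filtered [epochset()] on the channel set the bank
#'   was fitted on.
#' @param bank a `bci_csp` from [fit_csp()].
#' @param interval ms window (default: the bank's fitting interval).
#' @return Matrix trials x `length(bank$selected)`.
#' @export
csp_logvar <- function(ep, bank, interval = NULL) {
  stopifnot(inherits(ep, "bci_epochs"), inherits(bank, "bci_csp"))
  if (dim(ep$data)[2] != ncol(bank$filters))
    stop("channel count does not match the fitted bank")
  idx <- interval_index(ep, interval %||% bank$interval)
  w <- bank$filters[bank$selected, , drop = FALSE]
  out <- matrix(0, dim(ep$data)[1], nrow(w))
  floor_eps <- .Machine$double.eps
  floored <- FALSE
  for (tr in seq_len(nrow(out))) {
    s <- w %*% ep$data[tr, , idx, drop = TRUE]
    v <- rowMeans(s^2) - rowMeans(s)^2
    if (any(v < floor_eps)) { v <- pmax(v, floor_eps); floored <- TRUE }
    out[tr, ] <- log(v)
  }
  if (floored) warning("zero-variance component(s) floored at machine epsilon")
  out
}

interval_index <- function(ep, interval) {
  if (is.null(interval)) return(seq_along(ep$times))
  idx <- which(ep$times >= interval[1] & ep$times < interval[2])
  if (length(idx) == 0)
    stop("interval [", interval[1], ", ", interval[2],
         ") ms outside epoch times")
  idx
}
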