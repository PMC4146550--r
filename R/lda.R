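#' Train a shrinkage-regularized LDA
#'
#' Binary linear discriminant with the pooled covariance shrunk toward a
#' scaled identity, `(1 - gamma) * Sigma + gamma * nu * I` with
#' `nu = trace(Sigma) / d`. The shrinkage coefficient `gamma` is chosen by
#' the analytic (Ledoit-Wolf-style) estimator that minimizes the expected
#' squared Frobenius loss of the shrunk covariance -- essential in the
#' features-approximately-equal-to-trials regime typical of BCI calibration
#' data. The discriminant is
#' `w = Sigma_shrunk^-1 (mu2 - mu1)`, `b = -w' (mu1 + mu2) / 2`, so the
#' score `w'x + b` is negative for class 1 and positive for class 2.
#'
#' @param X numeric matrix, samples x features.
#' @param y per-sample class labels in `{1, 2}`; both classes need >= 2
#'   samples.
#' @param gamma optional fixed shrinkage coefficient in `[0, 1]`; default
#'   `NULL` = analytic estimate.
#' @return A `bci_lda` object: `mu1`, `mu2`, `sigma` (pooled, unshrunk),
#'   `gamma`, `w`, `b`, `dim`.
#' @export
train_shrinkage_lda <- function(X, y, gamma = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(1L, 2L))) stop("labels must be 1 or 2")
  n1 <- sum(y == 1L); n2 <- sum(y == 2L)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per class")
  mu1 <- colMeans(X[y == 1L, , drop = FALSE])
  mu2 <- colMeans(X[y == 2L, , drop = FALSE])
  Xc <- X
  Xc[y == 1L, ] <- sweep(X[y == 1L, , drop = FALSE], 2, mu1)
  Xc[y == 2L, ] <- sweep(X[y == 2L, , drop = FALSE], 2, mu2)
  n <- nrow(X)
  sigma <- crossprod(Xc) / (n - 1)
  if (is.null(gamma)) gamma <- analytic_shrinkage(Xc, sigma)
  m <- structure(list(mu1 = mu1, mu2 = mu2, sigma = sigma,
                      gamma = gamma, dim = ncol(X)),
                 class = "bci_lda")
  refit_lda(m)
}

# Ledoit-Wolf analytic shrinkage intensity toward nu * I,
# computed from class-centered samples Xc and their covariance S.
analytic_shrinkage <- function(Xc, S) {
  n <- nrow(Xc); d <- ncol(Xc)
  nu <- sum(diag(S)) / d
  # variance of the entries of the sample covariance
  Z2 <- Xc^2
  varS <- (crossprod(Z2) - n * (crossprod(Xc) / n)^2) * n / ((n - 1)^3)
  num <- sum(varS)
  den <- sum((S - diag(nu, d))^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

refit_lda <- function(m) {
  nu <- sum(diag(m$sigma)) / m$dim
  ss <- (1 - m$gamma) * m$sigma + diag(m$gamma * nu, m$dim)
  m$w <- as.numeric(solve(ss, m$mu2 - m$mu1))
  m$b <- -sum(m$w * (m$mu1 + m$mu2)) / 2
  m
}

#' @export
print.bci_lda <- function(x, ...) {
  cat(sprintf("<bci_lda> %d features, gamma = %.3f, |w| = %.3g\n",
              x$dim, x$gamma, sqrt(sum(x$w^2))))
  invisible(x)
}

#' Signed LDA score
#'
#' @param m a `bci_lda`.
#' @param x feature vector or samples x features matrix.
#' @return `w'x + b` per sample; negative = class 1, positive = class 2.
#' @export
lda_score <- function(m, x) {
  stopifnot(inherits(m, "bci_lda"))
  if (is.matrix(x)) {
    if (ncol(x) != m$dim) stop("feature dimension mismatch")
    return(as.numeric(x %*% m$w + m$b))
  }
  if (length(x) != m$dim) stop("feature dimension mismatch")
  sum(m$w * x) + m$b
}

#' Per-trial supervised adaptation state
#'
#' @param rate exponential update rate eta in `[0, 1]` (default 0.03, the
#'   package-wide per-trial adaptation rate).
#' @param enabled logical; adaptation is only legal in labeled (CopyTask)
#'   operation.
#' @return A `bci_adaptation` list with `rate`, `n_updates`, `enabled`.
#' @export
adaptation_state <- function(rate = 0.03, enabled = TRUE) {
  stopifnot(rate >= 0, rate <= 1)
  structure(list(rate = rate, n_updates = 0L, enabled = enabled),
            class = "bci_adaptation")
}

#' Supervised per-trial LDA adaptation
#'
#' After each labeled trial, the class mean of the true class and the pooled
#' covariance are re-estimated as exponential moving averages with rate
#' `st$rate`:
#' `mu_y <- (1 - eta) mu_y + eta x`;
#' `sigma <- (1 - eta) sigma + eta (x - mu_pool)(x - mu_pool)'` with
#' `mu_pool` the post-update mean of the two class means. `w` and `b` are
#' recomputed from the updated moments (the shrinkage coefficient is frozen
#' after initial training), so bias correction under drifting features is
#' implicit in the recomputed `b`.
#'
#' @param m a `bci_lda`.
#' @param st a [adaptation_state()]; must be enabled.
#' @param x observed feature vector.
#' @param y_true known class label (1 or 2).
#' @return List with updated `model` and `state`.
#' @export
adapt <- function(m, st, x, y_true) {
  stopifnot(inherits(m, "bci_lda"), inherits(st, "bci_adaptation"))
  if (!st$enabled)
    stop("adaptation is disabled (FreeMode runs without adaptation)")
  if (!y_true %in% c(1L, 2L)) stop("y_true must be 1 or 2")
  eta <- st$rate
  if (y_true == 1L) m$mu1 <- (1 - eta) * m$mu1 + eta * x
  else              m$mu2 <- (1 - eta) * m$mu2 + eta * x
  mu_pool <- (m$mu1 + m$mu2) / 2
  dev <- x - mu_pool
  m$sigma <- (1 - eta) * m$sigma + eta * tcrossprod(dev)
  st$n_updates <- st$n_updates + 1L
  list(model = refit_lda(m), state = st)
}
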