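# Deterministic fixtures built in code; no data files.

# Two-channel epochs whose per-trial sample covariance is exactly
# diag(4, 1) for class 1 and diag(1, 4) for class 2: channel signals are
# scaled orthogonal sinusoids over full periods (zero mean, unit variance,
# zero cross-covariance), so the CSP eigenvalues have the closed form
# {4/5, 1/5}.
toy_csp_epochs <- function(n_per_class = 4, nsamp = 200, fs = 100) {
  t <- seq_len(nsamp)
  c1 <- sqrt(2) * cos(2 * pi * 4 * t / nsamp)   # unit variance, 4 cycles
  s1 <- sqrt(2) * sin(2 * pi * 4 * t / nsamp)
  data <- array(0, c(2 * n_per_class, 2, nsamp))
  for (k in seq_len(n_per_class)) {
    data[k, 1, ] <- 2 * c1;  data[k, 2, ] <- s1        # cov diag(4,1)
    data[n_per_class + k, 1, ] <- c1
    data[n_per_class + k, 2, ] <- 2 * s1               # cov diag(1,4)
  }
  epochset(data, (t - 1) * 1000 / fs,
           rep(1:2, each = n_per_class), fs, c("chA", "chB"))
}

# Gaussian feature matrix with class means +/- delta/2 along the first axis
gauss_features <- function(n_per_class, d, delta = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * d), 2 * n_per_class, d)
  y <- rep(1:2, each = n_per_class)
  X[, 1] <- X[, 1] + ifelse(y == 1, -delta / 2, delta / 2)
  list(X = X, y = y)
}

# label-free gaussian epochs (null data) for leakage / chance checks
null_epochs <- function(n_trials = 60, nch = 8, nsamp = 200, fs = 100,
                        seed = 1) {
  set.seed(seed)
  data <- array(rnorm(n_trials * nch * nsamp), c(n_trials, nch, nsamp))
  epochset(data, (seq_len(nsamp) - 1) * 1000 / fs,
           rep(1:2, length.out = n_trials), fs)
}

# random legal Connect-4 board via a truncated random playout
random_board <- function(max_plies = 42) {
  g <- new_game()
  plies <- sample.int(max_plies, 1)
  for (i in seq_len(plies)) {
    if (g$status != "ongoing") break
    g <- hybridbci:::drop_coin(g, random_move(g))
  }
  g$board
}

# independent winner oracle: run-length scan of every row, column and
# diagonal (different algorithm from the 69-window scan in the package)
oracle_winner <- function(board) {
  lines <- list()
  for (r in 1:6) lines[[length(lines) + 1]] <- board[r, ]
  for (c in 1:7) lines[[length(lines) + 1]] <- board[, c]
  for (o in -5:6) {
    d1 <- board[col(board) - row(board) == o]
    d2 <- board[col(board) + row(board) == o + 7]
    if (length(d1) >= 4) lines[[length(lines) + 1]] <- d1
    if (length(d2) >= 4) lines[[length(lines) + 1]] <- d2
  }
  for (p in 1:2) {
    for (ln in lines) {
      r <- rle(ln)
      if (any(r$values == p & r$lengths >= 4)) return(paste0("win", p))
    }
  }
  if (all(board != 0)) "draw" else "ongoing"
}
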