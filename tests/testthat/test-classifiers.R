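test_that("shrinkage LDA recovers the closed-form discriminant", {
  # symmetric design: per class, points mu +/- e_i -> sample covariance
  # proportional to I, so w is proportional to mu2 - mu1 = (2, 0) for any
  # shrinkage, and b = 0 by symmetry
  mu1 <- c(-1, 0); mu2 <- c(1, 0)
  pts <- function(mu) rbind(mu + c(1, 0), mu - c(1, 0),
                            mu + c(0, 1), mu - c(0, 1))
  X <- rbind(pts(mu1), pts(mu2))
  y <- rep(1:2, each = 4)
  m <- train_shrinkage_lda(X, y)
  expect_equal(m$w[2], 0, tolerance = 1e-12)
  expect_gt(m$w[1], 0)
  expect_equal(m$b, 0, tolerance = 1e-12)
  expect_lt(lda_score(m, mu1), 0)
  expect_gt(lda_score(m, mu2), 0)
  expect_equal(lda_score(m, (mu1 + mu2) / 2), 0, tolerance = 1e-12)
})

test_that("gamma = 1 gives the nearest-mean direction", {
  g <- gauss_features(50, 3, delta = 1.5, seed = 2)
  m <- train_shrinkage_lda(g$X, g$y, gamma = 1)
  dmu <- colMeans(g$X[g$y == 2, ]) - colMeans(g$X[g$y == 1, ])
  nu <- sum(diag(m$sigma)) / 3
  expect_equal(m$w, dmu / nu, tolerance = 1e-9)
})

test_that("analytic shrinkage handles the n << d regime", {
  set.seed(4)
  X <- matrix(rnorm(5 * 20), 5, 20)
  y <- c(1, 1, 2, 2, 2)
  m <- train_shrinkage_lda(X, y)
  expect_gt(m$gamma, 0)
  expect_lte(m$gamma, 1)
  expect_true(all(is.finite(m$w)))
  # constant feature: covariance is singular, shrinkage keeps it solvable
  Xc <- cbind(X, 1)
  mc <- train_shrinkage_lda(Xc, y)
  expect_true(all(is.finite(mc$w)))
  expect_error(train_shrinkage_lda(X, rep(1, 5)), "labels|class")
})

test_that("LDA score is affine and translation moves only the bias", {
  g <- gauss_features(100, 4, seed = 5)
  m <- train_shrinkage_lda(g$X, g$y)
  x <- g$X[1, ]; d <- c(0.3, -1, 2, 0.1)
  expect_equal(lda_score(m, x + d) - lda_score(m, x), sum(m$w * d),
               tolerance = 1e-9)
  shift <- matrix(rep(c(5, -3, 2, 7), each = nrow(g$X)), ncol = 4)
  m2 <- train_shrinkage_lda(g$X + shift, g$y)
  expect_equal(m2$w, m$w, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(m2$b, m$b)))
  expect_error(lda_score(m, c(1, 2)), "dimension")
})

test_that("shrinkage path is continuous down to unregularized LDA", {
  g <- gauss_features(250, 6, delta = 1.2, seed = 6)   # n = 500, d = 6
  ho <- gauss_features(250, 6, delta = 1.2, seed = 7)
  acc <- function(gam) {
    m <- train_shrinkage_lda(g$X, g$y, gamma = gam)
    mean(ifelse(lda_score(m, ho$X) > 0, 2, 1) == ho$y)
  }
  expect_lt(abs(acc(1e-8) - acc(0)), 0.005)
})

test_that("adaptation follows the exponential moving-average closed form", {
  g <- gauss_features(30, 3, seed = 8)
  m0 <- train_shrinkage_lda(g$X, g$y)
  # rate 0: a no-op
  st0 <- adaptation_state(rate = 0)
  expect_equal(adapt(m0, st0, c(9, 9, 9), 1L)$model$mu1, m0$mu1)
  # n identical updates contract toward x* geometrically
  xstar <- c(2, -1, 0.5)
  eta <- 0.03                       # the default per-trial rate
  st <- adaptation_state()
  expect_equal(st$rate, eta)
  m <- m0
  for (i in 1:10) {
    up <- adapt(m, st, xstar, 1L)
    m <- up$model; st <- up$state
  }
  expect_equal(sqrt(sum((m$mu1 - xstar)^2)),
               (1 - eta)^10 * sqrt(sum((m0$mu1 - xstar)^2)),
               tolerance = 1e-9)
  expect_identical(st$n_updates, 10L)
  # w and b were refit from the updated moments
  expect_false(isTRUE(all.equal(m$w, m0$w)))
  # gamma frozen after initial training
  expect_identical(m$gamma, m0$gamma)
})

test_that("adaptation is refused when disabled (FreeMode contract)", {
  g <- gauss_features(10, 2, seed = 9)
  m <- train_shrinkage_lda(g$X, g$y)
  st <- adaptation_state(enabled = FALSE)
  expect_error(adapt(m, st, c(0, 0), 1L), "FreeMode|disabled")
})

test_that("meta-combination reduces to its members at the weight extremes", {
  meta10 <- meta_classifier(1, 0)
  expect_equal(combine(meta10, 0.7, -3), 0.7)
  meta <- meta_classifier(0.3, 0.7)
  expect_equal(combine(meta, 0.5, 0.5), 0.5)   # identical member outputs
  expect_equal(meta$w_osc + meta$w_slow, 1)
  # standardization divides member scores before weighting
  metas <- meta_classifier(0.5, 0.5, scale_osc = 2, scale_slow = 4)
  expect_equal(combine(metas, 2, 4), 1)
  expect_error(meta_classifier(-1, 0.5), "nonnegative")
})

test_that("combining two informative branches is not worse than the best", {
  # two independent evidence channels; seed-averaged combined accuracy
  # must reach max(single branches) - 1 percentage point
  accs <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 400
    y <- rep(1:2, each = n / 2)
    sgn <- ifelse(y == 1, -1, 1)
    s_osc <- sgn * 1.0 + rnorm(n)
    s_slow <- sgn * 0.8 + rnorm(n)
    meta <- meta_classifier(0.5, 0.5)
    comb <- combine(meta, s_osc, s_slow)
    c(osc = mean((s_osc > 0) == (y == 2)),
      slow = mean((s_slow > 0) == (y == 2)),
      comb = mean((comb > 0) == (y == 2)))
  })
  m <- rowMeans(accs)
  expect_gte(m["comb"], max(m["osc"], m["slow"]) - 0.01)
})

test_that("threshold gating partitions the real line into three intervals", {
  pol <- decision_policy(theta = 0)
  expect_identical(decide(pol, -0.2), "select_next_column")
  expect_identical(decide(pol, 0.2), "place_coin")
  expect_identical(decide(pol, 0), "noDecision")     # closed boundary
  pol1 <- decision_policy(theta = 1)
  expect_identical(decide(pol1, 1), "noDecision")
  expect_identical(decide(pol1, -1), "noDecision")
  pinf <- decision_policy(theta = Inf)
  expect_identical(decide(pinf, 1e12), "noDecision")
  expect_error(decision_policy(theta = -1))
})

test_that("raising theta never converts a noDecision into a decision", {
  set.seed(13)
  scores <- rnorm(200)
  thetas <- sort(c(0, abs(scores), 2 * max(abs(scores))))
  prev_decided <- rep(TRUE, length(scores))
  for (th in thetas) {
    decided <- vapply(scores, function(s)
      decide(decision_policy(th), s) != "noDecision", TRUE)
    expect_true(all(decided <= prev_decided))
    prev_decided <- decided
  }
})

test_that("theta calibration reaches the requested precision when possible", {
  set.seed(14)
  y <- rep(1:2, each = 100)
  sc <- ifelse(y == 1, -1, 1) + rnorm(200, sd = 0.8)
  pol <- calibrate_theta(sc, y, target_precision = 0.9)
  decided <- abs(sc) > pol$theta
  correct <- (sign(sc) == ifelse(y == 1, -1, 1))
  expect_gte(mean(correct[decided]), 0.9)
  # theta is the smallest candidate achieving it
  smaller <- sort(unique(c(0, abs(sc))))
  smaller <- smaller[smaller < pol$theta]
  if (length(smaller)) {
    th2 <- max(smaller)
    d2 <- abs(sc) > th2
    expect_lt(mean(correct[d2]), 0.9)
  }
})
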