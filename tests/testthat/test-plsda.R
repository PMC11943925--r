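test_that("scale_matrix centers and applies uv/pareto/none scaling", {
  X <- cbind(a = c(1, 3), b = c(2, 2))
  expect_warning(sc <- scale_matrix(X, "uv"), "zero-variance")
  expect_equal(unname(sc$values[, 1]), c(-0.7071068, 0.7071068),
               tolerance = 1e-6)

  X2 <- matrix(rnorm(20), 5, 4)
  expect_equal(unname(colMeans(scale_matrix(X2, "none")$values)),
               rep(0, 4), tolerance = 1e-12)

  X3 <- cbind(x = c(0, 4, 8, 12))   # sd != 4, construct sd exactly 4
  X3 <- cbind(x = c(-4, 0, 4) / sd(c(-4, 0, 4)) * 4)
  sc3 <- scale_matrix(X3, "pareto")
  expect_equal(sd(X3[, 1]), 4)
  expect_equal(unname(sc3$values[, 1]), unname(X3[, 1] - mean(X3[, 1])) / 2)

  expect_error(scale_matrix(matrix(1, 1, 2)), "2 rows")
})

test_that("a single perfectly predictive column gives R2Y(cum) = 1", {
  y <- rep(c("control", "study"), each = 4)
  X <- cbind(ifelse(y == "study", 1, -1) + 0)
  m <- fit_plsda(X, y, ncomp = 1, scaling = "none")
  expect_equal(m$r2y_cum, 1, tolerance = 1e-12)
})

test_that("the first NIPALS weight vector is proportional to X'y", {
  set.seed(6)
  X <- matrix(rnorm(24), 6, 4)
  y <- rep(c("control", "study"), 3)
  m <- fit_plsda(X, y, ncomp = 1, scaling = "uv")
  sc <- scale_matrix(X, "uv")
  yc <- ifelse(y == "study", 1, -1); yc <- yc - mean(yc)
  w <- drop(crossprod(sc$values, yc)); w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  expect_equal(unname(m$weights[, 1]), unname(w), tolerance = 1e-12)
})

test_that("scores match an independent reference PLS implementation", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(7)
  X <- matrix(rnorm(200), 20, 10)
  y <- rep(c("control", "study"), each = 10)
  m <- fit_plsda(X, y, ncomp = 2, scaling = "uv")
  ref <- mixOmics::pls(X, ifelse(y == "study", 1, -1), ncomp = 2,
                       scale = TRUE, mode = "regression")
  for (a in 1:2) {
    t1 <- m$scores[, a]; t2 <- ref$variates$X[, a]
    s <- sign(sum(t1 * t2))      # sign convention may differ per component
    expect_lt(max(abs(t1 - s * t2)), 1e-8)
  }
})

test_that("score vectors are mutually orthogonal and deflation is exact", {
  set.seed(9)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- rep(c("control", "study"), length.out = 15)
  m <- fit_plsda(X, y, ncomp = 4, scaling = "uv")
  G <- crossprod(m$scores)
  nrm <- sqrt(diag(G))
  off <- abs(G - diag(diag(G))) / tcrossprod(nrm)
  expect_lt(max(off), 1e-8)

  # after rank(X) components the deflated X residual vanishes
  rk <- qr(scale(X))$rank
  mf <- fit_plsda(X, y, ncomp = rk, scaling = "uv")
  sc <- scale_matrix(X, "uv")$values
  resid <- sc - tcrossprod(mf$scores, mf$loadings)
  expect_lt(sqrt(sum(resid^2)), 1e-8)
})

test_that("refitting identical inputs reproduces the model bit-for-bit", {
  set.seed(10)
  X <- matrix(rnorm(80), 16, 5)
  y <- rep(c("control", "study"), each = 8)
  m1 <- fit_plsda(X, y); m2 <- fit_plsda(X, y)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$scores, m2$scores)
  # sign convention: largest-magnitude weight entry is positive
  expect_true(all(apply(m1$weights, 2,
                        function(w) w[which.max(abs(w))] > 0)))
})

test_that("ncomp beyond the rank of X is rejected", {
  X <- cbind(1:6, (1:6) * 2 + rnorm(6, 0, 1e-14))
  y <- rep(c("control", "study"), 3)
  expect_error(fit_plsda(X, y, ncomp = 2), "rank")
})

test_that("VIP scores satisfy their algebraic identities and a hand calculation", {
  # A = 1 with all |w_k| equal: every VIP is exactly 1
  y <- rep(c(-1, 1), each = 4)
  X <- cbind(y + 0, y + 0, y + 0) + matrix(rnorm(24, 0, 1e-9), 8, 3)
  m <- fit_plsda(X, rep(c("control", "study"), each = 4), ncomp = 1,
                 scaling = "uv")
  expect_equal(unname(m$vip), rep(1, 3), tolerance = 1e-3)

  # mean squared VIP is 1 on random instances
  set.seed(12)
  for (i in 1:5) {
    Xr <- matrix(rnorm(14 * 9), 14, 9)
    mr <- fit_plsda(Xr, rep(c("control", "study"), 7), ncomp = 3)
    expect_equal(mean(mr$vip^2), 1, tolerance = 1e-9)
  }

  # 2-component K=3 toy: hand-apply the weighted-weights formula
  set.seed(14)
  Xt <- matrix(rnorm(30), 10, 3)
  mt <- fit_plsda(Xt, rep(c("control", "study"), 5), ncomp = 2)
  ss <- mt$y_loadings^2 * colSums(mt$scores^2)
  hand <- sqrt(3 * (mt$weights[, 1]^2 * ss[1] + mt$weights[, 2]^2 * ss[2]) /
                 sum(ss))
  expect_equal(unname(mt$vip), unname(hand), tolerance = 1e-12)
})

test_that("Q2 is high for separable data and low for permuted labels", {
  set.seed(15)
  n <- 14; K <- 10
  y <- rep(c("control", "study"), each = n / 2)
  shift <- ifelse(y == "study", 10, 0)
  X <- matrix(rnorm(n * K), n, K) + cbind(shift, shift, shift,
                                          matrix(0, n, K - 3))
  expect_gt(cross_validate_q2(X, y, ncomp = 2), 0.9)

  # permuted labels on pure noise: Q2 near or below zero almost always
  low <- 0
  for (i in 1:15) {
    Xn <- matrix(rnorm(28 * 12), 28, 12)
    yp <- sample(rep(c("control", "study"), each = 14))
    low <- low + (cross_validate_q2(Xn, yp, ncomp = 2) <= 0.05)
  }
  expect_gte(low / 15, 0.9)
})

test_that("Q2 does not exceed R2Y on matched components (soft property)", {
  set.seed(16)
  worse <- 0
  for (i in 1:10) {
    n <- 21; K <- 8
    y <- rep(c("control", "study"), length.out = n)
    X <- matrix(rnorm(n * K), n, K) +
      outer(ifelse(y == "study", 1, -1), rnorm(K))
    m <- fit_plsda(X, y, ncomp = 2)
    q2 <- cross_validate_q2(X, y, ncomp = 2)
    worse <- worse + (q2 <= m$r2y_cum + 1e-9)
  }
  expect_gte(worse, 9)
})

test_that("cross-validation folds interleave within class and guard sizes", {
  set.seed(17)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- rep(c("control", "study"), each = 5)
  expect_error(cross_validate_q2(X, y, n_folds = 7), "reduce n_folds")
  expect_true(is.finite(cross_validate_q2(X, y, n_folds = 5)))
})
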