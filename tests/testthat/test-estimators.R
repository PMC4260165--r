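test_that("fit_mlr solves the normal equations and recovers noise-free signal", {
  d <- toy_signal_data(n = 25, p = 5, n_signal = 2, noise_sd = 0, seed = 4)
  est <- fit_mlr(d, subset = c(1, 2))
  expect_equal(est$beta, c(3, 3, 0, 0, 0), tolerance = 1e-12)
  expect_null(est$intercept)

  # independently coded normal-equations oracle (explicit Gram inverse)
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  dd <- dataset(X, y)
  sub <- c(2, 4, 5)
  est2 <- fit_mlr(dd, sub)
  G <- t(X[, sub]) %*% X[, sub]
  oracle <- solve(G) %*% t(X[, sub]) %*% y
  expect_equal(est2$beta[sub], drop(oracle), tolerance = 1e-10)
  expect_equal(est2$beta[-sub], rep(0, 3))

  # empty subset: mean-only model
  est0 <- fit_mlr(dd, integer(0))
  expect_equal(est0$beta, rep(0, 6))
  expect_equal(predict_and_mse(est0, dd)$predictions, rep(mean(y), 40))

  # infeasible fit is a distinct signal, not an ordinary argument error
  small <- dataset(X[1:3, ], y[1:3])
  expect_error(fit_mlr(small, 1:4), class = "dcv_infeasible")
})

test_that("fit_mlr residuals are orthogonal to every included column", {
  set.seed(21)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- rnorm(50)
  d <- dataset(X, y)
  est <- fit_mlr(d, c(1, 3, 6, 8))
  r <- y - drop(X %*% est$beta)
  for (j in c(1, 3, 6, 8)) {
    expect_lt(abs(sum(X[, j] * r)) / sqrt(sum(X[, j]^2) * sum(r^2)), 1e-8)
  }
})

test_that("fit_pcr equals OLS at full rank and handles degeneracies", {
  set.seed(31)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  d <- dataset(X, y)
  sub <- c(1, 2, 4)
  full <- fit_pcr(d, sub, rank = 3)
  ols <- fit_mlr(d, sub, intercept = TRUE)
  expect_equal(full$beta, ols$beta, tolerance = 1e-8)
  expect_equal(full$intercept, ols$intercept, tolerance = 1e-8)

  # orthogonal columns, rank 1: single direction = the top singular component;
  # verify against an explicit SVD-by-hand oracle
  Q <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3))) * sqrt(40)
  Q <- sweep(Q, 2, c(3, 1, 0.5), "*")  # distinct column scales
  y2 <- rnorm(40)
  d2 <- dataset(Q, y2)
  est1 <- fit_pcr(d2, 1:3, rank = 1)
  Xc <- sweep(Q, 2, colMeans(Q))
  sv <- svd(Xc)
  bo <- sv$v[, 1] * (sum(sv$u[, 1] * (y2 - mean(y2))) / sv$d[1])
  expect_equal(est1$beta, drop(bo), tolerance = 1e-10)

  # duplicate column within the subset: finite coefficients, and the
  # duplicated direction carries the same information as a single copy
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  dd <- dataset(Xd, y)
  dup <- fit_pcr(dd, 1:2, rank = 1)
  expect_true(all(is.finite(dup$beta)))
  single <- fit_pcr(dd, 1L, rank = 1)
  expect_equal(drop(Xd %*% dup$beta) + dup$intercept,
               drop(Xd %*% single$beta) + single$intercept,
               tolerance = 1e-8)

  expect_error(fit_pcr(d, sub, rank = 4), "rank")
  expect_error(fit_pcr(d, sub, rank = 0), "rank")
})

test_that("fit_pcr training error is non-increasing in rank", {
  set.seed(41)
  pop <- make_population("sim2")
  d <- sample_dataset(pop, n = 40, seed = 41)
  mses <- vapply(1:6, function(r) {
    predict_and_mse(fit_pcr(d, 1:8, rank = r), d)$mse
  }, numeric(1))
  expect_true(all(diff(mses) <= 1e-12))
})

test_that("fit_lasso matches OLS at zero penalty and dies at the path maximum", {
  set.seed(51)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- drop(X %*% c(1, -2, 0, 0)) + rnorm(60, sd = 0.3)
  d <- dataset(X, y)
  l0 <- fit_lasso(d, penalty = 0)
  ols <- fit_mlr(d, 1:4)
  expect_equal(l0$beta, ols$beta, tolerance = 1e-4)

  lam_max <- max(abs(crossprod(X, y))) / nrow(X)
  ldead <- fit_lasso(d, penalty = lam_max * 1.0001)
  expect_equal(ldead$beta, rep(0, 4))
  expect_length(ldead$subset, 0)
})

test_that("fit_lasso agrees with a brute-force coordinate-descent oracle", {
  set.seed(61)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- drop(X %*% c(1.5, 0, -0.8)) + rnorm(50, sd = 0.5)
  d <- dataset(X, y)
  n <- nrow(X)
  lam <- 0.1
  # cyclic coordinate descent on (1/2n)||y - Xb||^2 + lam ||b||_1
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  b <- rep(0, 3)
  for (it in 1:5000) {
    b_old <- b
    for (j in 1:3) {
      r <- y - X[, -j, drop = FALSE] %*% b[-j]
      b[j] <- soft(sum(X[, j] * r) / n, lam) / (sum(X[, j]^2) / n)
    }
    if (max(abs(b - b_old)) < 1e-12) break
  }
  est <- fit_lasso(d, penalty = lam)
  expect_equal(est$beta, b, tolerance = 1e-6)
})

test_that("fit_lasso L1 norm is non-increasing in the penalty", {
  set.seed(71)
  pop <- make_population("sim2")
  d <- sample_dataset(pop, n = 60, seed = 71)
  norms <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4),
                  function(l) sum(abs(fit_lasso(d, l)$beta)), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("knn_predict honours exact neighbours, the full-neighbourhood limit, and a sort oracle", {
  set.seed(81)
  X <- matrix(rnorm(10 * 3), 10, 3)
  y <- rnorm(10)
  d <- dataset(X, y)

  expect_equal(knn_predict(d, X[4, , drop = FALSE], 1:3, k = 1), y[4])
  expect_equal(knn_predict(d, matrix(rnorm(6), 2, 3), 1:3, k = 10),
               rep(mean(y), 2))

  # exhaustive distance-sort oracle on a random 10-point instance
  Q <- matrix(rnorm(4 * 3), 4, 3)
  sub <- c(1, 3)
  mu <- colMeans(X[, sub]); s <- apply(X[, sub], 2, sd)
  Xs <- sweep(sweep(X[, sub], 2, mu), 2, s, "/")
  Qs <- sweep(sweep(Q[, sub], 2, mu), 2, s, "/")
  oracle <- apply(Qs, 1, function(q) {
    dist <- sqrt(colSums((t(Xs) - q)^2))
    mean(y[order(dist, seq_along(dist))[1:3]])
  })
  expect_equal(knn_predict(d, Q, sub, k = 3), oracle, tolerance = 1e-12)

  expect_error(knn_predict(d, Q, integer(0), k = 1), "non-empty")
})

test_that("predict_and_mse computes the mean squared residual", {
  d <- toy_signal_data(n = 20, p = 3, n_signal = 1, noise_sd = 0, seed = 5)
  est <- fit_mlr(d, 1)
  expect_equal(predict_and_mse(est, d)$mse, 0, tolerance = 1e-20)

  set.seed(91)
  big <- dataset(matrix(rnorm(1e5), ncol = 1), rnorm(1e5))
  zero <- coefficient_estimate(0, integer(0))
  expect_equal(predict_and_mse(zero, big)$mse, 1, tolerance = 0.02)

  one <- dataset(matrix(2, 1, 1), 5)
  est1 <- coefficient_estimate(1, 1L)
  expect_equal(predict_and_mse(est1, one)$mse, 9)

  expect_error(predict_and_mse(est1, d), "dimension")
})
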