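#' Coefficient estimate container
#'
#' Full-length coefficient vector with zeros at excluded positions, plus the
#' subset it was fitted on and technique-specific tuning (PCR rank, Lasso
#' penalty) and an optional intercept.
#'
#' @param beta length-`p` numeric vector.
#' @param subset ordered integer vector of 1-based included predictor indices.
#' @param rank PCR rank or `NULL`.
#' @param penalty Lasso penalty or `NULL`.
#' @param intercept intercept or `NULL` (no-intercept fit).
#' @return an object of class `dcv_coef`.
#' @export
coefficient_estimate <- function(beta, subset, rank = NULL, penalty = NULL,
                                 intercept = NULL) {
  beta <- as.numeric(beta)
  subset <- as.integer(subset)
  stopifnot(all(beta[setdiff(seq_along(beta), subset)] == 0))
  if (!is.null(rank)) stopifnot(rank >= 1, rank <= max(1L, length(subset)))
  structure(list(beta = beta, subset = subset, rank = rank,
                 penalty = penalty, intercept = intercept),
            class = "dcv_coef")
}

#' Ordinary least-squares fit on a variable subset
#'
#' Fits `y ~ X[, subset]` by least squares and embeds the coefficients in a
#' length-`p` vector with zeros for excluded predictors.  The empty subset is
#' legal and denotes the mean-only model (all-zero coefficients, intercept =
#' training mean).  Simulation mode (`intercept = FALSE`) fits through the
#' origin; rank-deficient restricted matrices are fitted by minimum-norm
#' least squares.
#'
#' @param train a `dcv_dataset`.
#' @param subset integer vector of 1-based predictor indices (may be empty).
#' @param intercept fit an intercept (centering)?  Default `FALSE`.
#' @return a `dcv_coef`.
#' @export
fit_mlr <- function(train, subset, intercept = FALSE) {
  stopifnot(inherits(train, "dcv_dataset"))
  p <- ncol(train$X)
  subset <- sort(as.integer(subset))
  stopifnot(all(subset >= 1), all(subset <= p))
  n <- nrow(train$X)
  beta <- numeric(p)
  if (length(subset) == 0) {
    return(coefficient_estimate(beta, subset, intercept = mean(train$y)))
  }
  if (length(subset) >= n) {
    stop_infeasible("restricted matrix has at least as many columns as rows")
  }
  Xs <- train$X[, subset, drop = FALSE]
  y <- train$y
  icpt <- NULL
  if (intercept) {
    mu <- colMeans(Xs)
    Xs <- sweep(Xs, 2, mu)
    ybar <- mean(y)
    y <- y - ybar
  }
  G <- crossprod(Xs)
  g <- crossprod(Xs, y)
  bs <- tryCatch(drop(solve(G, g)),
                 error = function(e) {
                   # minimum-norm solution via the pseudoinverse of the Gram
                   ev <- eigen(G, symmetric = TRUE)
                   pos <- ev$values > max(ev$values) * 1e-12
                   drop(ev$vectors[, pos, drop = FALSE] %*%
                          ((t(ev$vectors[, pos, drop = FALSE]) %*% g) /
                             ev$values[pos]))
                 })
  beta[subset] <- bs
  if (intercept) icpt <- ybar - drop(crossprod(mu, bs))
  coefficient_estimate(beta, subset, intercept = icpt)
}

#' Principal component regression on a variable subset
#'
#' Regresses the (centered) response on the first `rank` principal-component
#' scores of the centered restricted matrix and maps the coefficients back to
#' the original predictor coordinates.  Components with negligible singular
#' value are skipped, so collinear subsets yield finite coefficients.
#'
#' @param train a `dcv_dataset`.
#' @param subset integer vector of 1-based predictor indices (non-empty).
#' @param rank number of components, `1 <= rank <= min(|subset|, n - 1)`.
#' @param scale. autoscale the restricted columns (real-data mode)?
#' @return a `dcv_coef` with an intercept (centering absorbs the mean).
#' @export
fit_pcr <- function(train, subset, rank, scale. = FALSE) {
  stopifnot(inherits(train, "dcv_dataset"))
  p <- ncol(train$X)
  subset <- sort(as.integer(subset))
  n <- nrow(train$X)
  stopifnot(length(subset) >= 1, all(subset >= 1), all(subset <= p))
  if (rank < 1 || rank > min(length(subset), n - 1)) {
    stop("'rank' must lie in 1..min(|subset|, n - 1)")
  }
  Xs <- train$X[, subset, drop = FALSE]
  mu <- colMeans(Xs)
  Xs <- sweep(Xs, 2, mu)
  scl <- rep(1, length(subset))
  if (scale.) {
    scl <- apply(Xs, 2, sd)
    scl[scl < 1e-12] <- 1
    Xs <- sweep(Xs, 2, scl, "/")
  }
  ybar <- mean(train$y)
  yc <- train$y - ybar
  sv <- svd(Xs)
  tol <- sv$d[1] * 1e-10
  use <- seq_len(rank)
  use <- use[sv$d[use] > tol]
  bs <- numeric(length(subset))
  if (length(use) > 0) {
    alpha <- drop(crossprod(sv$u[, use, drop = FALSE], yc)) / sv$d[use]
    bs <- drop(sv$v[, use, drop = FALSE] %*% alpha)
  }
  bs <- bs / scl
  beta <- numeric(p)
  beta[subset] <- bs
  coefficient_estimate(beta, subset, rank = as.integer(rank),
                       intercept = ybar - drop(crossprod(mu, bs)))
}

#' L1-penalised least squares (Lasso)
#'
#' Solves the Lasso problem at a given penalty via the glmnet path solver;
#' the subset is defined by the non-zero coefficients.  Simulation mode uses
#' no intercept and no standardisation (data are generated centered/scaled).
#'
#' @param train a `dcv_dataset`.
#' @param penalty nonnegative penalty (glmnet `lambda` scale:
#'   `(1/2n)||y - Xb||^2 + penalty * ||b||_1`).
#' @param intercept,standardize passed to the solver; defaults are the
#'   simulation-mode conventions.
#' @return a `dcv_coef` with `penalty` recorded.
#' @export
fit_lasso <- function(train, penalty, intercept = FALSE, standardize = FALSE) {
  stopifnot(inherits(train, "dcv_dataset"), penalty >= 0)
  p <- ncol(train$X)
  fit <- glmnet::glmnet(train$X, train$y, alpha = 1, intercept = intercept,
                        standardize = standardize, thresh = 1e-14)
  cf <- coef(fit, s = penalty, exact = TRUE, x = train$X, y = train$y,
             alpha = 1, intercept = intercept, standardize = standardize,
             thresh = 1e-14)
  beta <- as.numeric(cf)[-1]
  icpt <- if (intercept) as.numeric(cf)[1] else NULL
  coefficient_estimate(beta, which(beta != 0), penalty = penalty,
                       intercept = icpt)
}

#' k-nearest-neighbour regression prediction
#'
#' Each query prediction is the unweighted mean of the responses of its `k`
#' nearest training rows by Euclidean distance in the autoscaled subset
#' space (training-set means and standard deviations are applied to the
#' query rows; no leakage).  Distance ties are broken by lower training-row
#' index.
#'
#' @param train a `dcv_dataset` (the neighbour reference).
#' @param query_X matrix of query rows (all `p` columns).
#' @param subset non-empty integer vector of predictor indices.
#' @param k number of neighbours, `1 <= k <= nrow(train$X)`.
#' @return numeric prediction vector, one value per query row.
#' @export
knn_predict <- function(train, query_X, subset, k) {
  stopifnot(inherits(train, "dcv_dataset"))
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("kNN requires a non-empty subset")
  n <- nrow(train$X)
  stopifnot(k >= 1, k <= n)
  Xs <- train$X[, subset, drop = FALSE]
  Q <- as.matrix(query_X)[, subset, drop = FALSE]
  mu <- colMeans(Xs)
  scl <- apply(Xs, 2, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(Xs, 2, mu), 2, scl, "/")
  Q <- sweep(sweep(Q, 2, mu), 2, scl, "/")
  # squared distances query x train via the expansion ||q||^2 - 2 q.x + ||x||^2
  d2 <- outer(rowSums(Q^2), rowSums(Xs^2), "+") - 2 * tcrossprod(Q, Xs)
  apply(d2, 1, function(row) {
    nb <- order(row, seq_len(n))[seq_len(k)]  # ties: lower row index first
    mean(train$y[nb])
  })
}

#' Predict from a coefficient estimate and compute the mean squared error
#'
#' @param est a `dcv_coef`.
#' @param data a `dcv_dataset` with `ncol(X) == length(est$beta)`.
#' @return a list with `predictions` and `mse`.
#' @export
predict_and_mse <- function(est, data) {
  stopifnot(inherits(est, "dcv_coef"), inherits(data, "dcv_dataset"))
  if (ncol(data$X) != length(est$beta)) {
    stop("dimension mismatch between estimate and data")
  }
  pred <- drop(data$X %*% est$beta) + (est$intercept %||% 0)
  list(predictions = pred, mse = mean((data$y - pred)^2))
}
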