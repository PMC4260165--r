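#' AR(1) covariance matrix
#'
#' Entry (i, j) equals `rho^|i - j|`: the covariance of a first-order
#' autoregressive process with unit marginal variance.  Positive definite for
#' `0 <= rho < 1`.
#'
#' @param p number of variables (>= 1).
#' @param rho autocorrelation coefficient in `[0, 1)`.
#' @return a `p x p` symmetric matrix with unit diagonal.
#' @export
ar1_covariance <- function(p, rho) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 1, p == round(p))
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1) {
    stop("'rho' must be a single value in [0, 1)")
  }
  idx <- seq_len(p)
  rho^abs(outer(idx, idx, "-"))
}

#' Construct a population specification for the simulation study
#'
#' The data-generating process is `y = X b + e` with `X` row-wise Gaussian
#' with covariance `V = ar1_covariance(p, rho)` and `e ~ N(0, sigma2)`.
#' Two built-in populations carry sparse coefficient vectors with two
#' symmetric clusters of non-zero entries:
#' \describe{
#'   \item{`"sim1"`}{two strong predictors, `b[7] = b[14] = 1.077`.}
#'   \item{`"sim2"`}{six weaker, correlated predictors,
#'     `b[6] = b[8] = b[13] = b[15] = 0.343` and `b[7] = b[14] = 0.686`.}
#' }
#' Defaults: `p = 21`, `n = 80`, `rho = 0.5`, `sigma2 = 1`.
#'
#' @param model_label `"sim1"`, `"sim2"`, or `"custom"`.
#' @param p,n,rho,sigma2 population dimensions and noise variance.
#' @param b coefficient vector, required (length `p`) for `"custom"`.
#' @return an object of class `dcv_population` with fields `p`, `n`, `rho`,
#'   `sigma2`, `b`, `V`, `V_sqrt` (symmetric matrix square root of `V`) and
#'   `model_label`.
#' @export
make_population <- function(model_label = c("sim1", "sim2", "custom"),
                            p = 21L, n = 80L, rho = 0.5, sigma2 = 1.0,
                            b = NULL) {
  model_label <- match.arg(model_label)
  stopifnot(p >= 1, n >= 1, sigma2 > 0)
  if (model_label == "sim1") {
    stopifnot(p >= 14)
    b <- numeric(p)
    b[c(7, 14)] <- 1.077
  } else if (model_label == "sim2") {
    stopifnot(p >= 15)
    b <- numeric(p)
    b[c(6, 8, 13, 15)] <- 0.343
    b[c(7, 14)] <- 0.686
  } else {
    if (is.null(b)) stop("'custom' population requires a coefficient vector 'b'")
    stopifnot(length(b) == p)
    b <- as.numeric(b)
  }
  V <- ar1_covariance(p, rho)
  ev <- eigen(V, symmetric = TRUE)
  # symmetric (eigen) square root, not Cholesky: orientation-free map
  V_sqrt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  structure(list(p = as.integer(p), n = as.integer(n), rho = rho,
                 sigma2 = sigma2, b = b, V = V, V_sqrt = V_sqrt,
                 model_label = model_label),
            class = "dcv_population")
}

#' Population R-squared implied by a population specification
#'
#' `b' V b / (b' V b + sigma2)`: the fraction of response variance explained
#' by the true signal.
#'
#' @param pop a `dcv_population`.
#' @return a single number in `[0, 1)`.
#' @export
population_r2 <- function(pop) {
  stopifnot(inherits(pop, "dcv_population"))
  s <- drop(crossprod(pop$b, pop$V %*% pop$b))
  s / (s + pop$sigma2)
}

#' Construct a dataset
#'
#' The unit consumed by every modelling stage: an `n x p` predictor matrix
#' and a length-`n` response.
#'
#' @param X numeric matrix.
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param feature_names optional length-`p` character vector.
#' @param ids optional length-`n` character vector of object identifiers.
#' @return an object of class `dcv_dataset`.
#' @export
dataset <- function(X, y, feature_names = NULL, ids = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == ncol(X))
    colnames(X) <- feature_names
  }
  if (!is.null(ids)) stopifnot(length(ids) == nrow(X))
  structure(list(X = X, y = y,
                 feature_names = feature_names %||% colnames(X),
                 ids = ids),
            class = "dcv_dataset")
}

#' @export
print.dcv_dataset <- function(x, ...) {
  cat(sprintf("<dcv_dataset: %d objects x %d predictors>\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

subset_rows <- function(data, idx) {
  dataset(data$X[idx, , drop = FALSE], data$y[idx],
          feature_names = data$feature_names,
          ids = if (!is.null(data$ids)) data$ids[idx])
}

#' Draw a training sample from a population
#'
#' `X = Z %*% V^{1/2}` with `Z` i.i.d. standard normal entries (symmetric
#' matrix square root), `y = X b + e`, `e ~ N(0, sigma2)`.  Identical
#' `(pop, n, seed)` yields bit-identical output.
#'
#' @param pop a `dcv_population`.
#' @param n sample size (default `pop$n`).
#' @param seed integer seed (mandatory: reproducibility is part of the
#'   contract).
#' @return a `dcv_dataset`.
#' @export
sample_dataset <- function(pop, n = pop$n, seed) {
  stopifnot(inherits(pop, "dcv_population"), n >= 1)
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  Z <- matrix(rnorm(n * pop$p), nrow = n, ncol = pop$p)
  X <- Z %*% pop$V_sqrt
  e <- rnorm(n, sd = sqrt(pop$sigma2))
  dataset(X, drop(X %*% pop$b) + e,
          feature_names = paste0("x", seq_len(pop$p)))
}

#' Draw a large oracle test set from a population
#'
#' Same generator as [sample_dataset()], but on a seed stream that is
#' deterministically decoupled from the training stream so that an oracle set
#' and a training sample drawn with the same user seed share no rows.
#'
#' @param pop a `dcv_population`.
#' @param n_oracle oracle size (default 5000).
#' @param seed integer seed.
#' @return a `dcv_dataset` with `n_oracle` rows.
#' @export
sample_oracle <- function(pop, n_oracle = 5000L, seed) {
  if (missing(seed)) stop("'seed' is required")
  sample_dataset(pop, n = n_oracle, seed = derive_seed(seed, 900017L))
}

#' Write / read a dataset as CSV
#'
#' Header row, one `id` column, the descriptor columns, and a response column
#' named `y`.  Numbers are written with 17 significant digits so a
#' write-read round trip is value-exact.
#'
#' @param data a `dcv_dataset`.
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   `dcv_dataset`.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "dcv_dataset"))
  nm <- data$feature_names %||% paste0("x", seq_len(ncol(data$X)))
  df <- data.frame(id = data$ids %||% as.character(seq_along(data$y)),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(data$X))) {
    df[[nm[j]]] <- sprintf("%.17g", data$X[, j])
  }
  df$y <- sprintf("%.17g", data$y)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(df), "y" %in% names(df))
  pred <- setdiff(names(df), c("id", "y"))
  X <- as.matrix(df[pred])
  storage.mode(X) <- "double"
  dataset(X, as.numeric(df$y), feature_names = pred,
          ids = as.character(df$id))
}
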