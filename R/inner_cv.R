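#' Inner-loop cross-validation design
#'
#' Three resampling schemes for the inner loop of double cross-validation:
#' leave-one-out (`"LOO"`), leave-multiple-out (`"LMO"`, leaving out a
#' fraction `leave_out_fraction` of the training rows as validation set,
#' repeated `n_repeats` times with random splits), and `"KFOLD"`.
#'
#' @param scheme `"LOO"`, `"LMO"` or `"KFOLD"`.
#' @param leave_out_fraction the left-out fraction `d` in `(0, 1)` (LMO only).
#' @param n_repeats number of random LMO splits (default 50).
#' @param n_folds number of folds (KFOLD only).
#' @return an object of class `dcv_design`.
#' @export
cv_design <- function(scheme = c("LOO", "LMO", "KFOLD"),
                      leave_out_fraction = NULL, n_repeats = 50L,
                      n_folds = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "LMO") {
    stopifnot(is.numeric(leave_out_fraction), length(leave_out_fraction) == 1,
              leave_out_fraction > 0, leave_out_fraction < 1,
              n_repeats >= 1)
    out <- list(scheme = scheme, leave_out_fraction = leave_out_fraction,
                n_repeats = as.integer(n_repeats))
  } else if (scheme == "KFOLD") {
    stopifnot(is.numeric(n_folds), n_folds >= 2)
    out <- list(scheme = scheme, n_folds = as.integer(n_folds))
  } else {
    out <- list(scheme = scheme)
  }
  structure(out, class = "dcv_design")
}

#' @export
print.dcv_design <- function(x, ...) {
  lab <- switch(x$scheme,
                LOO = "leave-one-out",
                LMO = sprintf("leave-%d%%-out, %d repeats",
                              round(100 * x$leave_out_fraction), x$n_repeats),
                KFOLD = sprintf("%d-fold", x$n_folds))
  cat(sprintf("<dcv_design: %s>\n", lab))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Generate inner-loop construction/validation splits
#'
#' Deterministic given `seed`.  LOO enumerates all `n_train` single-object
#' validation sets; LMO draws validation sets of size
#' `round(d * n_train)` (half-up) uniformly at random without replacement,
#' independently across repeats; KFOLD randomly permutes the indices and cuts
#' contiguous chunks whose sizes differ by at most one.
#'
#' @param n_train number of training rows (>= 3).
#' @param design a `dcv_design`.
#' @param seed integer seed (ignored by LOO, which is deterministic).
#' @return an object of class `dcv_splits`: a list with `pairs` (list of
#'   `list(construction =, validation =)` index vectors) and `parent_n`.
#' @export
make_inner_splits <- function(n_train, design, seed = 1L) {
  stopifnot(n_train >= 3, inherits(design, "dcv_design"))
  idx <- seq_len(n_train)
  if (design$scheme == "LOO") {
    pairs <- lapply(idx, function(i) list(construction = idx[-i],
                                          validation = i))
  } else if (design$scheme == "LMO") {
    n_val <- round_half_up(design$leave_out_fraction * n_train)
    n_val <- max(1L, as.integer(n_val))
    if (n_train - n_val < 2) {
      stop("construction set would have fewer than 2 rows")
    }
    set.seed(seed)
    pairs <- lapply(seq_len(design$n_repeats), function(r) {
      val <- sort(sample.int(n_train, n_val))
      list(construction = setdiff(idx, val), validation = val)
    })
  } else {  # KFOLD
    k <- design$n_folds
    if (k > n_train) stop("more folds than training rows")
    sizes <- rep(n_train %/% k, k)
    rem <- n_train %% k
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    set.seed(seed)
    perm <- sample.int(n_train)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    pairs <- lapply(seq_len(k), function(f) {
      val <- sort(perm[starts[f]:ends[f]])
      list(construction = setdiff(idx, val), validation = val)
    })
  }
  structure(list(pairs = pairs, parent_n = as.integer(n_train)),
            class = "dcv_splits")
}

splits_to_cpp <- function(splits) {
  list(con = lapply(splits$pairs, function(p) as.integer(p$construction) - 1L),
       val = lapply(splits$pairs, function(p) as.integer(p$validation) - 1L))
}

#' Cross-validated objective of a candidate model
#'
#' Refits the candidate on every construction set and returns the mean
#' squared validation error (total squared validation residuals divided by
#' the total validation count; for equal-sized validation sets this is the
#' spec'd `sum ss / (n_inner * n_val)`).  Infeasible fits (MLR with
#' `|subset| >= n_constr`) propagate as `+Inf`, never as an error.
#'
#' @param train a `dcv_dataset` (the training rows of one outer partition).
#' @param splits a `dcv_splits` over `nrow(train$X)`.
#' @param candidate a list with `technique` (`"MLR"`, `"PCR"` or `"KNN"`),
#'   `subset`, and `rank` (PCR) or `k` (KNN).
#' @param intercept center construction data (real-data mode)?
#' @param scale. autoscale PCR columns (real-data mode)?
#' @return a single number (possibly `Inf`).
#' @export
cv_objective <- function(train, splits, candidate, intercept = FALSE,
                         scale. = FALSE) {
  stopifnot(inherits(train, "dcv_dataset"), inherits(splits, "dcv_splits"))
  stopifnot(splits$parent_n == nrow(train$X))
  technique <- match.arg(candidate$technique, c("MLR", "PCR", "KNN"))
  subset <- sort(as.integer(candidate$subset))
  sp <- splits_to_cpp(splits)
  if (technique == "MLR" || length(subset) == 0) {
    return(cpp_cv_mlr(train$X, train$y, sp$con, sp$val, subset - 1L,
                      intercept, FALSE))
  }
  if (technique == "PCR") {
    per_rank <- cpp_cv_pcr(train$X, train$y, sp$con, sp$val, subset - 1L,
                           scale.)
    r <- candidate$rank
    if (is.null(r)) return(if (length(per_rank)) min(per_rank) else Inf)
    if (r < 1 || r > length(per_rank)) return(Inf)
    return(per_rank[r])
  }
  # KNN: refit-by-reference; validation rows scored against construction rows
  k <- candidate$k
  stopifnot(!is.null(k), k >= 1)
  ss <- 0
  cnt <- 0
  for (pair in splits$pairs) {
    con <- pair$construction
    val <- pair$validation
    if (k > length(con)) return(Inf)
    con_data <- subset_rows(train, con)
    pred <- knn_predict(con_data, train$X[val, , drop = FALSE], subset, k)
    ss <- ss + sum((train$y[val] - pred)^2)
    cnt <- cnt + length(val)
  }
  ss / cnt
}

# kNN objective for all k = 1..k_max in one pass (used by the SA selector):
# neighbours are ordered once per split, cumulative means give every k.
knn_cv_objective_allk <- function(train, splits, subset, k_max) {
  subset <- as.integer(subset)
  ss <- numeric(k_max)
  cnt <- 0
  for (pair in splits$pairs) {
    con <- pair$construction
    val <- pair$validation
    if (k_max > length(con)) return(rep(Inf, k_max))
    Xs <- train$X[con, subset, drop = FALSE]
    mu <- colMeans(Xs)
    scl <- apply(Xs, 2, sd)
    scl[scl < 1e-12] <- 1
    Xs <- sweep(sweep(Xs, 2, mu), 2, scl, "/")
    Q <- sweep(sweep(train$X[val, subset, drop = FALSE], 2, mu), 2, scl, "/")
    d2 <- outer(rowSums(Q^2), rowSums(Xs^2), "+") - 2 * tcrossprod(Q, Xs)
    yc <- train$y[con]
    for (i in seq_along(val)) {
      ord <- order(d2[i, ], seq_along(con))[seq_len(k_max)]
      pred_k <- cumsum(yc[ord]) / seq_len(k_max)
      ss <- ss + (train$y[val[i]] - pred_k)^2
    }
    cnt <- cnt + length(val)
  }
  ss / cnt
}
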