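filter_report <- function(p, kept, removed_idx, reason, detail) {
  removed <- data.frame(index = as.integer(removed_idx),
                        reason = as.character(reason),
                        detail = as.numeric(detail),
                        stringsAsFactors = FALSE)
  structure(list(kept = as.integer(kept), removed = removed, p = as.integer(p)),
            class = "dcv_filter_report")
}

#' @export
print.dcv_filter_report <- function(x, ...) {
  cat(sprintf("<filter report: kept %d of %d columns, removed %d>\n",
              length(x$kept), x$p, nrow(x$removed)))
  invisible(x)
}

#' Zero / near-zero variance filter
#'
#' Constant columns are always removed (`zero_variance`).  A column is
#' removed as `near_zero_variance` when the ratio of the most frequent value
#' count to the second most frequent value count exceeds `near_zero_ratio`
#' AND the fraction of distinct values is below `unique_cut` -- the
#' frequency-ratio rule; the thresholds are configurable because published
#' pipelines name the step without defining it.
#'
#' @param data a `dcv_dataset`.
#' @param near_zero_ratio frequency-ratio threshold (default 19).
#' @param unique_cut distinct-value fraction threshold (default 0.1).
#' @return a `dcv_filter_report`.
#' @export
variance_filter <- function(data, near_zero_ratio = 19, unique_cut = 0.1) {
  stopifnot(inherits(data, "dcv_dataset"), near_zero_ratio >= 0)
  X <- data$X
  n <- nrow(X)
  removed_idx <- integer(0); reason <- character(0); detail <- numeric(0)
  for (j in seq_len(ncol(X))) {
    freq <- sort(table(X[, j]), decreasing = TRUE)
    if (length(freq) == 1) {
      removed_idx <- c(removed_idx, j)
      reason <- c(reason, "zero_variance")
      detail <- c(detail, 0)
      next
    }
    ratio <- as.numeric(freq[1]) / as.numeric(freq[2])
    if (ratio > near_zero_ratio && length(freq) / n < unique_cut) {
      removed_idx <- c(removed_idx, j)
      reason <- c(reason, "near_zero_variance")
      detail <- c(detail, ratio)
    }
  }
  filter_report(ncol(X), setdiff(seq_len(ncol(X)), removed_idx),
                removed_idx, reason, detail)
}

#' Pairwise correlation filter
#'
#' Greedy scan in column order: a column is removed when its absolute Pearson
#' correlation with any earlier kept column exceeds `threshold` (the later
#' column of each offending pair loses; deterministic).  After filtering, no
#' kept pair exceeds the threshold.
#'
#' @param data a `dcv_dataset`.
#' @param threshold correlation threshold in `(0, 1]` (0.9 and 0.8 are the
#'   published choices for the two real-data workflows).
#' @return a `dcv_filter_report`.
#' @export
correlation_filter <- function(data, threshold) {
  stopifnot(inherits(data, "dcv_dataset"), threshold > 0, threshold <= 1)
  C <- abs(cor(data$X))
  p <- ncol(data$X)
  kept <- integer(0)
  removed_idx <- integer(0); detail <- numeric(0)
  for (j in seq_len(p)) {
    if (length(kept) > 0 && any(C[kept, j] > threshold)) {
      removed_idx <- c(removed_idx, j)
      detail <- c(detail, max(C[kept, j]))
    } else {
      kept <- c(kept, j)
    }
  }
  filter_report(p, kept, removed_idx,
                rep("high_correlation", length(removed_idx)), detail)
}

#' CAR scores (correlation-adjusted marginal correlations)
#'
#' `P^{-1/2} rho_xy`, where `P` is the predictor correlation matrix (symmetric
#' inverse square root) and `rho_xy` the marginal predictor--response
#' correlations: whitening removes the redundancy among correlated
#' predictors before ranking them by relevance.
#'
#' @param data a `dcv_dataset` with more than 2 rows and non-constant columns.
#' @return a length-`p` numeric vector of scores.
#' @export
car_scores <- function(data) {
  stopifnot(inherits(data, "dcv_dataset"), nrow(data$X) > 2)
  P <- cor(data$X)
  rho <- drop(cor(data$X, data$y))
  ev <- eigen(P, symmetric = TRUE)
  vals <- ev$values
  if (min(vals) < 1e-10) {
    warning("singular predictor correlation matrix; using a regularized inverse square root")
    vals <- pmax(vals, 1e-8)
  }
  drop(ev$vectors %*% ((t(ev$vectors) %*% rho) / sqrt(vals)))
}

#' CAR-score preselection
#'
#' Ranks columns by absolute CAR score and returns the `n_high` top-ranked
#' plus the `n_low` bottom-ranked column indices (published defaults: 5 high
#' and 45 low, so that the preselected pool contains both relevant and
#' insignificant predictors).
#'
#' @param data a `dcv_dataset`.
#' @param n_high,n_low counts, `n_high + n_low <= p`.
#' @return sorted integer vector of selected column indices.
#' @export
car_preselect <- function(data, n_high = 5L, n_low = 45L) {
  p <- ncol(data$X)
  if (n_high + n_low > p) stop("'n_high' + 'n_low' exceeds the column count")
  ord <- order(abs(car_scores(data)), decreasing = TRUE)
  sort(c(if (n_high > 0) ord[seq_len(n_high)],
         if (n_low > 0) ord[seq(p - n_low + 1L, p)]))
}

#' Apply a filter report to a dataset
#'
#' @param data a `dcv_dataset`.
#' @param report a `dcv_filter_report` (or an integer vector of columns).
#' @return the reduced `dcv_dataset`.
#' @export
apply_filter <- function(data, report) {
  kept <- if (inherits(report, "dcv_filter_report")) report$kept
          else as.integer(report)
  dataset(data$X[, kept, drop = FALSE], data$y,
          feature_names = (data$feature_names %||%
                             paste0("x", seq_len(ncol(data$X))))[kept],
          ids = data$ids)
}
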