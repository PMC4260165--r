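# Shared fixtures, built in code at test time.

# Tiny dataset with a strong linear signal on the first `n_signal` columns.
toy_signal_data <- function(n = 30, p = 4, n_signal = 2, b_strength = 3,
                            noise_sd = 0.1, seed = 101) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  b <- c(rep(b_strength, n_signal), rep(0, p - n_signal))
  y <- drop(X %*% b) + rnorm(n, sd = noise_sd)
  dataset(X, y)
}

# Exhaustive subset enumeration oracle: minimises cv_objective over all 2^p
# subsets with the given splits (test-only; never a production selector).
exhaustive_best_subset <- function(train, splits, technique = "MLR") {
  p <- ncol(train$X)
  best <- list(obj = Inf, subset = integer(0), rank = NULL)
  for (code in 0:(2^p - 1)) {
    subset <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    obj <- cv_objective(train, splits,
                        list(technique = technique, subset = subset))
    if (obj < best$obj) best <- list(obj = obj, subset = subset)
  }
  best
}

# Monte-Carlo standard error helper: 3-sigma band around zero for a paired
# difference vector.
within_3se_of_zero <- function(d) {
  abs(mean(d)) <= 3 * sd(d) / sqrt(length(d))
}

# Minimal selected-model stub for hand-built outer records.
selected_model_for_test <- function(subset, technique = "MLR", rank = NULL) {
  doublecv:::selected_model(technique, subset, inner_cv_error = NA_real_,
                            rank = rank)
}
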