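#' Expected coefficient vector of a fitted subset model
#'
#' Conditioned on the selected configuration `(technique, subset, rank)` and
#' the training size.  For MLR under a jointly Gaussian design the
#' expectation is exact and analytic: the restricted coefficients converge in
#' expectation to `b_a + V_aa^{-1} V_a,ac b_ac` (omitted-variable formula;
#' `a` = subset, `ac` = complement), embedded into a length-`p` vector with
#' zeros outside the subset.  For PCR (or as a cross-check for MLR) a
#' Monte-Carlo estimator averages fitted coefficients over `n_mc` fresh
#' training sets of size `n_train` with the configuration held fixed.
#'
#' @param pop a `dcv_population`.
#' @param technique `"MLR"` or `"PCR"`.
#' @param subset integer vector of included predictors.
#' @param rank PCR rank (ignored for MLR).
#' @param n_train training size (Monte Carlo only).
#' @param method `"analytic"` (MLR only) or `"monte_carlo"`.
#' @param n_mc Monte-Carlo replications (default 2000).
#' @param seed integer seed for the Monte-Carlo stream.
#' @return a length-`p` numeric vector, zero outside `subset`.
#' @export
expected_coefficients <- function(pop, technique = c("MLR", "PCR"), subset,
                                  rank = NULL, n_train = pop$n,
                                  method = c("analytic", "monte_carlo"),
                                  n_mc = 2000L, seed = 1L) {
  technique <- match.arg(technique)
  method <- match.arg(method)
  stopifnot(inherits(pop, "dcv_population"))
  subset <- sort(as.integer(subset))
  p <- pop$p
  if (length(subset) == 0) return(numeric(p))
  if (method == "analytic") {
    if (technique != "MLR") {
      stop("the analytic expectation is available for MLR only")
    }
    comp <- setdiff(seq_len(p), subset)
    eb <- numeric(p)
    eb[subset] <- pop$b[subset] +
      if (length(comp)) {
        drop(solve(pop$V[subset, subset, drop = FALSE],
                   pop$V[subset, comp, drop = FALSE] %*% pop$b[comp]))
      } else 0
    return(eb)
  }
  acc <- numeric(p)
  for (i in seq_len(n_mc)) {
    train <- sample_dataset(pop, n = n_train, seed = derive_seed(seed, 6L, i))
    est <- if (technique == "MLR") fit_mlr(train, subset)
           else fit_pcr(train, subset, rank = rank)
    acc <- acc + est$beta
  }
  acc / n_mc
}

#' Expectation table: cached expected coefficients per selected configuration
#'
#' Repeated subsets across outer partitions are computed once; entries are
#' keyed by `(technique, subset, rank, n_train)`.
#'
#' @param pop a `dcv_population`.
#' @param method `"analytic"` (MLR) or `"monte_carlo"`.
#' @param n_mc Monte-Carlo replications per entry.
#' @param seed integer seed.
#' @return an object of class `dcv_expectations` (environment-backed cache).
#' @export
expectation_table <- function(pop, method = c("analytic", "monte_carlo"),
                              n_mc = 2000L, seed = 1L) {
  method <- match.arg(method)
  structure(list(pop = pop, method = method, n_mc = as.integer(n_mc),
                 seed = as.integer(seed), cache = new.env(parent = emptyenv())),
            class = "dcv_expectations")
}

lookup_expectation <- function(tab, technique, subset, rank, n_train) {
  key <- paste(technique, paste(subset, collapse = ","),
               rank %||% "NA", n_train, sep = "|")
  if (!is.null(tab$cache[[key]])) return(tab$cache[[key]])
  method <- if (technique == "PCR") "monte_carlo" else tab$method
  eb <- expected_coefficients(tab$pop, technique, subset, rank = rank,
                              n_train = n_train, method = method,
                              n_mc = tab$n_mc,
                              seed = derive_seed(tab$seed, 7L, length(subset)))
  tab$cache[[key]] <- eb
  eb
}

#' Bias--variance decomposition of the coefficient estimates
#'
#' Over the outer records: `mse_b` = mean ||b_hat_k - b||^2, `var_b` = mean
#' ||b_hat_k - E b_hat_k||^2, `bias_b` = mean ||E b_hat_k - b||^2, each
#' expectation conditioned on the configuration selected in partition `k`.
#' The cross term is not forced to zero, so `mse_b = bias_b + var_b` holds
#' only in expectation.
#'
#' @param records the `records` of a `dcv_result` (MLR/PCR techniques).
#' @param expectations a `dcv_expectations`.
#' @param pop a `dcv_population`.
#' @return named numeric vector `c(mse_b, bias_b, var_b)`.
#' @export
coef_decomposition <- function(records, expectations, pop) {
  stopifnot(inherits(expectations, "dcv_expectations"),
            inherits(pop, "dcv_population"))
  terms <- vapply(records, function(r) {
    if (anyNA(r$beta)) stop("coefficient decomposition needs MLR/PCR records")
    # analytic MLR expectations do not depend on n_train; Monte-Carlo PCR
    # entries are conditioned at the population's nominal sample size
    eb <- lookup_expectation(expectations, r$selected$technique,
                             r$selected$subset, r$selected$rank,
                             n_train = pop$n)
    c(sum((r$beta - pop$b)^2),
      sum((eb - pop$b)^2),
      sum((r$beta - eb)^2))
  }, numeric(3))
  c(mse_b = mean(terms[1, ]), bias_b = mean(terms[2, ]),
    var_b = mean(terms[3, ]))
}

#' Bias--variance decomposition of the model error on test data
#'
#' `me_dcv` = mean_k ||X_test,k (b_hat_k - b)||^2 / n_test, with `var_me` and
#' `bias_me` the analogous quadratic forms around the conditional
#' expectation.
#'
#' @param records the `records` of a `dcv_result`.
#' @param expectations a `dcv_expectations`.
#' @param pop a `dcv_population`.
#' @param partitions the `partitions` of the same `dcv_result`.
#' @param sample the `dcv_dataset` the result was computed on.
#' @return named numeric vector `c(me_dcv, bias_me, var_me)`.
#' @export
me_decomposition <- function(records, expectations, pop, partitions, sample) {
  stopifnot(length(records) == length(partitions))
  terms <- vapply(seq_along(records), function(k) {
    r <- records[[k]]
    Xt <- sample$X[partitions[[k]]$test_idx, , drop = FALSE]
    eb <- lookup_expectation(expectations, r$selected$technique,
                             r$selected$subset, r$selected$rank,
                             n_train = pop$n)
    nt <- nrow(Xt)
    c(sum((Xt %*% (r$beta - pop$b))^2) / nt,
      sum((Xt %*% (eb - pop$b))^2) / nt,
      sum((Xt %*% (r$beta - eb))^2) / nt)
  }, numeric(3))
  c(me_dcv = mean(terms[1, ]), bias_me = mean(terms[2, ]),
    var_me = mean(terms[3, ]))
}

#' Theoretical model error of a coefficient vector
#'
#' `(beta - b)' V (beta - b)`: the exact model error under the population
#' covariance, i.e. with the population replacing random test data.  The
#' theoretical prediction error adds the irreducible noise:
#' `pe_theo = me_theo + sigma2`.
#'
#' @param beta length-`p` coefficient vector.
#' @param pop a `dcv_population`.
#' @return a single nonnegative number.
#' @export
me_theo <- function(beta, pop) {
  stopifnot(inherits(pop, "dcv_population"), length(beta) == pop$p)
  d <- beta - pop$b
  drop(crossprod(d, pop$V %*% d))
}

#' Relative deviation of an error estimate from its theoretical value
#'
#' `100 * (ave_pe - ave_pe_theo) / ave_pe_theo` (percent; underestimation is
#' negative).
#'
#' @param ave_pe averaged prediction-error estimate.
#' @param ave_pe_theo averaged theoretical prediction error (> 0).
#' @return a single number (percent).
#' @export
rel_dev <- function(ave_pe, ave_pe_theo) {
  if (!is.finite(ave_pe_theo) || ave_pe_theo <= 0) {
    stop("'ave_pe_theo' must be positive")
  }
  100 * (ave_pe - ave_pe_theo) / ave_pe_theo
}

#' Average figures of merit over simulation repeats
#'
#' Arithmetic mean plus standard deviation and standard error per column.
#'
#' @param per_simulation a data frame (or numeric matrix), one row per
#'   simulation repeat.
#' @return a data frame with columns `statistic`, `mean`, `sd`, `se`, `n`.
#' @export
study_average <- function(per_simulation) {
  df <- as.data.frame(per_simulation)
  num <- df[vapply(df, is.numeric, logical(1))]
  stopifnot(nrow(num) >= 1)
  n <- nrow(num)
  data.frame(statistic = names(num),
             mean = vapply(num, mean, numeric(1)),
             sd = if (n > 1) vapply(num, sd, numeric(1)) else rep(0, ncol(num)),
             se = if (n > 1) vapply(num, sd, numeric(1)) / sqrt(n)
                  else rep(0, ncol(num)),
             n = n, row.names = NULL)
}

#' Full decomposition of a double-CV run against a known population
#'
#' Convenience wrapper combining [coef_decomposition()],
#' [me_decomposition()] and the theoretical errors into one record.
#'
#' @param result a `dcv_result` computed with an MLR/PCR selector.
#' @param sample the `dcv_dataset` it was computed on.
#' @param pop the generating `dcv_population`.
#' @param method,n_mc,seed passed to [expectation_table()].
#' @return a list of class `dcv_decomposition` with fields `mse_b`, `bias_b`,
#'   `var_b`, `me_dcv`, `bias_me`, `var_me`, `me_theo_dcv`, `pe_theo_dcv`.
#' @export
decompose_dcv <- function(result, sample, pop,
                          method = c("analytic", "monte_carlo"),
                          n_mc = 2000L, seed = 1L) {
  stopifnot(inherits(result, "dcv_result"))
  method <- match.arg(method)
  tab <- expectation_table(pop, method = method, n_mc = n_mc, seed = seed)
  cd <- coef_decomposition(result$records, tab, pop)
  md <- me_decomposition(result$records, tab, pop, result$partitions, sample)
  met <- mean(vapply(result$records, function(r) me_theo(r$beta, pop),
                     numeric(1)))
  structure(c(as.list(cd), as.list(md),
              list(me_theo_dcv = met, pe_theo_dcv = met + pop$sigma2)),
            class = "dcv_decomposition")
}
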