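#' Selector configurations for the outer loop
#'
#' A selector configuration tells [run_double_cv()] how to pick a model on
#' each training set: tabu search over subsets (`selector_remts`), Lasso
#' penalty selection (`selector_lasso`), simulated-annealing kNN
#' (`selector_saknn`), or a pinned configuration that is never searched
#' (`selector_fixed`, used for decomposition studies and tests).
#'
#' @param technique `"MLR"` or `"PCR"` (tabu search / fixed).
#' @param n_iterations tabu-search iterations.
#' @param start_subset tabu-search start state (default empty).
#' @param n_folds folds for the Lasso inner CV (default 10).
#' @param params a `dcv_saknn_params`.
#' @param subset,rank,k pinned configuration for `selector_fixed`.
#' @return an object of class `dcv_selector`.
#' @name selectors
NULL

#' @rdname selectors
#' @export
selector_remts <- function(technique = c("MLR", "PCR"), n_iterations,
                           start_subset = integer(0)) {
  technique <- match.arg(technique)
  structure(list(kind = "remts", technique = technique,
                 params = tabu_params(n_iterations, start_subset)),
            class = "dcv_selector")
}

#' @rdname selectors
#' @export
selector_lasso <- function(n_folds = 10L) {
  structure(list(kind = "lasso", technique = "LASSO",
                 n_folds = as.integer(n_folds)),
            class = "dcv_selector")
}

#' @rdname selectors
#' @export
selector_saknn <- function(params = saknn_params()) {
  structure(list(kind = "saknn", technique = "KNN", params = params),
            class = "dcv_selector")
}

#' @rdname selectors
#' @export
selector_fixed <- function(technique = c("MLR", "PCR", "KNN"),
                           subset, rank = NULL, k = NULL) {
  technique <- match.arg(technique)
  structure(list(kind = "fixed", technique = technique,
                 subset = sort(as.integer(subset)), rank = rank, k = k),
            class = "dcv_selector")
}

selector_label <- function(selector) {
  switch(selector$kind,
         remts = paste0("TS-", selector$technique),
         lasso = "LASSO",
         saknn = "SA-KNN",
         fixed = paste0("FIXED-", selector$technique))
}

# Run one selector on one training set.  Returns a dcv_selected.
select_model <- function(selector, train, design, seed, intercept = FALSE,
                         scale. = FALSE) {
  switch(selector$kind,
    remts = remts_select(train, design, selector$params, selector$technique,
                         seed = seed, intercept = intercept,
                         scale. = scale.)$model,
    lasso = lasso_select(train, n_folds = selector$n_folds, seed = seed,
                         intercept = intercept, standardize = scale.),
    saknn = saknn_select(train, design, selector$params, seed = seed),
    fixed = {
      splits <- make_inner_splits(nrow(train$X), design, seed)
      cand <- list(technique = selector$technique, subset = selector$subset,
                   rank = selector$rank, k = selector$k)
      err <- cv_objective(train, splits, cand, intercept = intercept,
                          scale. = scale.)
      selected_model(selector$technique, selector$subset, err,
                     rank = selector$rank,
                     n_neighbors = if (!is.null(selector$k)) as.integer(selector$k))
    })
}

# Refit a selected configuration on the full training set.
refit_model <- function(selector, model, train, intercept = FALSE,
                        scale. = FALSE) {
  switch(model$technique,
    MLR = fit_mlr(train, model$subset, intercept = intercept),
    PCR = if (length(model$subset) == 0) fit_mlr(train, integer(0))
          else fit_pcr(train, model$subset,
                       rank = min(model$rank, length(model$subset),
                                  nrow(train$X) - 1L), scale. = scale.),
    LASSO = attr(model, "fit") %||%
      fit_lasso(train, model$penalty, intercept = intercept,
                standardize = scale.),
    KNN = NULL)  # kNN has no coefficient form; prediction by reference
}

#' Outer train/test partitions
#'
#' With `n_test = 1` and `n_outer = n` the `n` leave-one-out partitions are
#' enumerated deterministically (every object tested exactly once); otherwise
#' each partition draws its test set uniformly at random without replacement,
#' independently across partitions (test sets of different partitions may
#' overlap).
#'
#' @param n number of objects.
#' @param n_test test-set size, `1 <= n_test < n`.
#' @param n_outer number of partitions (the simulation study uses 80).
#' @param seed integer seed.
#' @return a list of `n_outer` partitions, each
#'   `list(train_idx =, test_idx =, k =)`.
#' @export
outer_partitions <- function(n, n_test, n_outer = 80L, seed = 1L) {
  stopifnot(n_test >= 1, n_outer >= 1)
  if (n_test >= n) stop("'n_test' must be smaller than 'n'")
  idx <- seq_len(n)
  if (n_test == 1 && n_outer == n) {
    return(lapply(idx, function(i) list(train_idx = idx[-i], test_idx = i,
                                        k = i)))
  }
  set.seed(seed)
  lapply(seq_len(n_outer), function(k) {
    test <- sort(sample.int(n, n_test))
    list(train_idx = setdiff(idx, test), test_idx = test, k = k)
  })
}

#' Run repeated double cross-validation
#'
#' For each outer partition the selector is run on the training rows only;
#' the selected configuration is refit on the full training set and assessed
#' on the test rows (`pe_k` = mean squared test residual).  The selected
#' model's inner-CV error is kept as `internal_error_k`.  If an oracle set is
#' supplied, the refit model is additionally assessed on it; if the
#' population is known, the theoretical model error
#' `(beta - b)' V (beta - b)` is recorded per partition.
#'
#' @param sample a `dcv_dataset`.
#' @param selector a `dcv_selector`.
#' @param design a `dcv_design` for the inner loop.
#' @param n_test outer test-set size.
#' @param n_outer number of outer partitions.
#' @param seed integer seed; partitions and all inner splits derive from it.
#' @param oracle optional `dcv_dataset` used purely for assessment.
#' @param population optional `dcv_population` for theoretical errors.
#' @param mode `"simulation"` (no intercept, no scaling) or `"real"`
#'   (center/scale with construction-set statistics).
#' @return an object of class `dcv_result`: per-partition `records` plus the
#'   aggregates `pe_dcv`, `pe_internal_dcv`, `vb_pe`, and (when available)
#'   `pe_oracle_dcv`, `vb_pe_oracle`, `me_theo_dcv`, `pe_theo_dcv`.
#' @export
run_double_cv <- function(sample, selector, design, n_test, n_outer = 80L,
                          seed = 1L, oracle = NULL, population = NULL,
                          mode = c("simulation", "real")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "dcv_dataset"), inherits(selector, "dcv_selector"),
            inherits(design, "dcv_design"))
  intercept <- mode == "real"
  scale. <- mode == "real"
  n <- nrow(sample$X)
  p <- ncol(sample$X)
  partitions <- outer_partitions(n, n_test, n_outer, derive_seed(seed, 1L))
  records <- vector("list", length(partitions))
  for (k in seq_along(partitions)) {
    part <- partitions[[k]]
    train <- subset_rows(sample, part$train_idx)
    model <- select_model(selector, train, design,
                          seed = derive_seed(seed, 2L, k),
                          intercept = intercept, scale. = scale.)
    est <- refit_model(selector, model, train, intercept = intercept,
                       scale. = scale.)
    test <- subset_rows(sample, part$test_idx)
    if (model$technique == "KNN") {
      pred <- knn_predict(train, test$X, model$subset, model$n_neighbors)
      pe_k <- mean((test$y - pred)^2)
      beta <- rep(NA_real_, p)
      pe_oracle_k <- if (!is.null(oracle)) {
        po <- knn_predict(train, oracle$X, model$subset, model$n_neighbors)
        mean((oracle$y - po)^2)
      }
      me_theo_k <- NULL
    } else {
      pe_k <- predict_and_mse(est, test)$mse
      beta <- est$beta
      pe_oracle_k <- if (!is.null(oracle)) predict_and_mse(est, oracle)$mse
      me_theo_k <- if (!is.null(population)) me_theo(beta, population)
    }
    records[[k]] <- list(k = k, selected = model, beta = beta, pe_k = pe_k,
                         internal_error_k = model$inner_cv_error,
                         pe_oracle_k = pe_oracle_k, me_theo_k = me_theo_k)
  }
  pe <- vapply(records, `[[`, numeric(1), "pe_k")
  internal <- vapply(records, `[[`, numeric(1), "internal_error_k")
  out <- list(records = records, partitions = partitions,
              pe_dcv = mean(pe), pe_internal_dcv = mean(internal),
              vb_pe = mean((pe - mean(pe))^2),
              pe_oracle_dcv = NULL, vb_pe_oracle = NULL,
              me_theo_dcv = NULL, pe_theo_dcv = NULL,
              config_echo = list(selector = selector_label(selector),
                                 design = unclass(design), n_test = n_test,
                                 n_outer = as.integer(n_outer),
                                 seed = as.integer(seed), mode = mode))
  if (!is.null(oracle)) {
    peo <- vapply(records, `[[`, numeric(1), "pe_oracle_k")
    out$pe_oracle_dcv <- mean(peo)
    out$vb_pe_oracle <- mean((peo - mean(peo))^2)
  }
  if (!is.null(population) && selector$technique != "KNN") {
    met <- vapply(records, `[[`, numeric(1), "me_theo_k")
    out$me_theo_dcv <- mean(met)
    out$pe_theo_dcv <- out$me_theo_dcv + population$sigma2
  }
  structure(out, class = "dcv_result")
}

#' @export
print.dcv_result <- function(x, ...) {
  cat(sprintf("<dcv_result: %s, %d outer partitions>\n", x$config_echo$selector,
              length(x$records)))
  cat(sprintf("  PE_dcv       = %.4f\n", x$pe_dcv))
  cat(sprintf("  PE_internal  = %.4f\n", x$pe_internal_dcv))
  cat(sprintf("  vb(PE)       = %.4f\n", x$vb_pe))
  if (!is.null(x$pe_oracle_dcv)) {
    cat(sprintf("  PE_oracle    = %.4f\n", x$pe_oracle_dcv))
  }
  if (!is.null(x$pe_theo_dcv)) {
    cat(sprintf("  PE_theo      = %.4f\n", x$pe_theo_dcv))
  }
  invisible(x)
}

#' Per-variable selection frequencies across outer records
#'
#' @param results a `dcv_result` or a list of them.
#' @return numeric vector: `frequency[j]` is the fraction of all outer
#'   records whose selected subset contains variable `j`.
#' @export
variable_frequencies <- function(results) {
  if (inherits(results, "dcv_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  p <- length(results[[1]]$records[[1]]$beta)
  counts <- numeric(p)
  total <- 0
  for (res in results) {
    for (rec in res$records) {
      counts[rec$selected$subset] <- counts[rec$selected$subset] + 1
      total <- total + 1
    }
  }
  counts / total
}

#' Repeated sample/oracle partitioning driver
#'
#' Real-data workflow: repeatedly splits a full dataset into a working sample
#' and the complementary oracle set, runs double cross-validation on each
#' sample with the complement as oracle, and summarises the per-repeat
#' prediction-error estimates.
#'
#' @param full a `dcv_dataset`.
#' @param sample_size working-sample size (< `nrow(full$X)`).
#' @param n_repeats number of sample/oracle partitions.
#' @param selector,design,n_test,n_outer,mode passed to [run_double_cv()].
#' @param seed integer seed.
#' @return a list with `per_repeat` (data frame of `pe_dcv`,
#'   `pe_internal_dcv`, `pe_oracle_dcv`, `vb_pe` per repeat) and `summary`
#'   (mean and sd of each column).
#' @export
heavy_repeat_driver <- function(full, sample_size, n_repeats, selector,
                                design, n_test, n_outer = 100L, seed = 1L,
                                mode = "real") {
  stopifnot(inherits(full, "dcv_dataset"), sample_size < nrow(full$X))
  n <- nrow(full$X)
  rows <- lapply(seq_len(n_repeats), function(r) {
    set.seed(derive_seed(seed, 4L, r))
    sample_idx <- sort(sample.int(n, sample_size))
    work <- subset_rows(full, sample_idx)
    oracle <- subset_rows(full, setdiff(seq_len(n), sample_idx))
    res <- run_double_cv(work, selector, design, n_test, n_outer,
                         seed = derive_seed(seed, 5L, r), oracle = oracle,
                         mode = mode)
    data.frame(repeat_id = r, pe_dcv = res$pe_dcv,
               pe_internal_dcv = res$pe_internal_dcv,
               pe_oracle_dcv = res$pe_oracle_dcv, vb_pe = res$vb_pe)
  })
  per_repeat <- do.call(rbind, rows)
  num <- per_repeat[, -1, drop = FALSE]
  list(per_repeat = per_repeat,
       summary = data.frame(statistic = names(num),
                            mean = vapply(num, mean, numeric(1)),
                            sd = vapply(num, sd, numeric(1)),
                            row.names = NULL))
}

#' Write a double-CV result as CSV records plus a JSON summary
#'
#' One CSV row per outer record (partition counter, semicolon-joined subset,
#' tuning, errors) and a JSON file with the aggregates and the full
#' configuration echo, sufficient for bit-exact replay.
#'
#' @param result a `dcv_result`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return invisibly, the two file paths.
#' @export
write_dcv_result <- function(result, dir, stem = "dcv") {
  stopifnot(inherits(result, "dcv_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(result$records, function(r) {
    data.frame(k = r$k,
               subset = paste(r$selected$subset, collapse = ";"),
               rank = r$selected$rank %||% NA_integer_,
               penalty = r$selected$penalty %||% NA_real_,
               n_neighbors = r$selected$n_neighbors %||% NA_integer_,
               pe_k = r$pe_k, internal_error_k = r$internal_error_k,
               pe_oracle_k = r$pe_oracle_k %||% NA_real_)
  })
  csv_path <- file.path(dir, paste0(stem, "_records.csv"))
  write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  json_path <- file.path(dir, paste0(stem, "_summary.json"))
  summary <- list(pe_dcv = result$pe_dcv,
                  pe_internal_dcv = result$pe_internal_dcv,
                  vb_pe = result$vb_pe,
                  pe_oracle_dcv = result$pe_oracle_dcv,
                  vb_pe_oracle = result$vb_pe_oracle,
                  me_theo_dcv = result$me_theo_dcv,
                  pe_theo_dcv = result$pe_theo_dcv,
                  config = result$config_echo)
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
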