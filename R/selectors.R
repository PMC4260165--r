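#' Tabu-search parameters
#'
#' @param n_iterations number of tabu-search iterations (>= 1).  The
#'   simulation defaults used in the study are 12 for the two-variable
#'   population and 36 for the six-variable population.
#' @param start_subset starting subset (default empty: the search must
#'   justify every inclusion, and the empty-model objective -- the variance
#'   of `y` -- is the natural baseline).
#' @return an object of class `dcv_tabu_params`.
#' @export
tabu_params <- function(n_iterations, start_subset = integer(0)) {
  stopifnot(n_iterations >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 start_subset = sort(as.integer(start_subset))),
            class = "dcv_tabu_params")
}

#' Simulated-annealing kNN parameters
#'
#' Defaults are the published SA-kNN settings: starting temperature 60,
#' final temperature 1e-3, 1 descriptor mutated per step, 40 steps per
#' temperature, at most 5 neighbours, cooling factor 0.4, and subset sizes
#' 2..16.
#'
#' @param t_max,t_min start/final temperature.
#' @param m_mutate descriptors swapped per step.
#' @param n_steps_per_temp steps before each cooling.
#' @param k_max largest neighbour count scored.
#' @param cooling multiplicative cooling factor in `(0, 1)`.
#' @param d_min,d_max smallest/largest subset size searched.
#' @return an object of class `dcv_saknn_params`.
#' @export
saknn_params <- function(t_max = 60, t_min = 1e-3, m_mutate = 1L,
                         n_steps_per_temp = 40L, k_max = 5L, cooling = 0.4,
                         d_min = 2L, d_max = 16L) {
  stopifnot(t_min < t_max, cooling > 0, cooling < 1, d_min <= d_max,
            m_mutate >= 1, n_steps_per_temp >= 1, k_max >= 1)
  structure(list(t_max = t_max, t_min = t_min, m_mutate = as.integer(m_mutate),
                 n_steps_per_temp = as.integer(n_steps_per_temp),
                 k_max = as.integer(k_max), cooling = cooling,
                 d_min = as.integer(d_min), d_max = as.integer(d_max)),
            class = "dcv_saknn_params")
}

#' Temperature schedule of the SA-kNN search
#'
#' `t_max * cooling^j` for `j = 0, 1, ...` while the value is still `>= t_min`.
#'
#' @param params a `dcv_saknn_params`.
#' @return numeric vector of temperature levels, strictly decreasing.
#' @export
saknn_schedule <- function(params) {
  temps <- numeric(0)
  t <- params$t_max
  while (t >= params$t_min) {
    temps <- c(temps, t)
    t <- t * params$cooling
  }
  temps
}

selected_model <- function(technique, subset, inner_cv_error, rank = NULL,
                           penalty = NULL, n_neighbors = NULL) {
  structure(list(technique = technique, subset = sort(as.integer(subset)),
                 rank = rank, penalty = penalty, n_neighbors = n_neighbors,
                 inner_cv_error = inner_cv_error),
            class = "dcv_selected")
}

#' @export
print.dcv_selected <- function(x, ...) {
  extra <- c(if (!is.null(x$rank)) sprintf("rank=%d", x$rank),
             if (!is.null(x$penalty)) sprintf("penalty=%.4g", x$penalty),
             if (!is.null(x$n_neighbors)) sprintf("k=%d", x$n_neighbors))
  cat(sprintf("<%s model: {%s}%s, inner CV error %.4g>\n", x$technique,
              paste(x$subset, collapse = ","),
              if (length(extra)) paste0(" ", paste(extra, collapse = " ")) else "",
              x$inner_cv_error))
  invisible(x)
}

#' Reverse-elimination-method tabu search for MLR / PCR subset selection
#'
#' "Steepest descent, mildest ascent": per iteration every single-variable
#' flip (in -> out, out -> in) of the current subset is scored with the
#' cross-validated objective on a split set shared across all candidates; the
#' best non-tabu move is executed -- the most improving move if one exists,
#' otherwise the least worsening one.  Moves that would recreate an already
#' visited subset are tabu.  For PCR the rank is co-optimised: every
#' candidate subset is scored at all ranks `1..min(|subset|, n_constr - 1)`
#' and the best rank wins.  Returns the best configuration visited, not the
#' final state (the search accepts worsening moves).
#'
#' @param train a `dcv_dataset`.
#' @param design a `dcv_design` for the inner objective.
#' @param params a `dcv_tabu_params`.
#' @param technique `"MLR"` or `"PCR"`.
#' @param seed integer seed (drives the inner split set only; the search
#'   itself is deterministic).
#' @param intercept,scale. real-data mode flags (see [cv_objective()]).
#' @return a list with components `model` (a `dcv_selected`) and `trace`
#'   (visited subsets, objective per iteration, best subset/objective,
#'   moves evaluated).
#' @export
remts_select <- function(train, design, params, technique = c("MLR", "PCR"),
                         seed = 1L, intercept = FALSE, scale. = FALSE) {
  technique <- match.arg(technique)
  stopifnot(inherits(train, "dcv_dataset"), inherits(params, "dcv_tabu_params"))
  n <- nrow(train$X)
  stopifnot(n >= 4)
  splits <- make_inner_splits(n, design, seed)
  sp <- splits_to_cpp(splits)
  loo <- design$scheme == "LOO"  # exact hat-matrix shortcut applies
  res <- cpp_remts(train$X, train$y, sp$con, sp$val,
                   technique = if (technique == "MLR") 0L else 1L,
                   n_iterations = params$n_iterations,
                   start0 = params$start_subset - 1L,
                   centered = intercept, scale_cols = scale.,
                   loo_shortcut = loo)
  if (!is.finite(res$best_objective)) {
    stop("tabu search found no feasible configuration")
  }
  rank <- if (technique == "PCR" && length(res$best_subset) > 0 &&
              !is.na(res$best_rank)) res$best_rank
  model <- selected_model(technique, res$best_subset, res$best_objective,
                          rank = rank)
  trace <- list(visited = res$visited,
                objective_per_iteration = res$objective_per_iteration,
                best_subset = sort(as.integer(res$best_subset)),
                best_objective = res$best_objective,
                moves_evaluated = res$moves_evaluated)
  list(model = model, trace = trace)
}

#' Lasso penalty selection by k-fold cross-validation
#'
#' Evaluates the glmnet penalty path by `n_folds`-fold cross-validation with
#' a deterministic, seed-derived fold assignment, picks the penalty with the
#' minimal cross-validated MSE (no one-standard-error rule), and refits on
#' the whole training set at that penalty.
#'
#' @param train a `dcv_dataset`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param intercept,standardize solver conventions (simulation defaults).
#' @return a `dcv_selected` with `penalty` and the non-zero-coefficient
#'   subset; the fitted `dcv_coef` is attached as attribute `"fit"`.
#' @export
lasso_select <- function(train, n_folds = 10L, seed = 1L, intercept = FALSE,
                         standardize = FALSE) {
  stopifnot(inherits(train, "dcv_dataset"), n_folds >= 2)
  n <- nrow(train$X)
  stopifnot(n_folds <= n)
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))
  cvfit <- glmnet::cv.glmnet(train$X, train$y, alpha = 1, foldid = foldid,
                             intercept = intercept, standardize = standardize,
                             type.measure = "mse")
  lam <- cvfit$lambda.min
  est <- fit_lasso(train, lam, intercept = intercept,
                   standardize = standardize)
  model <- selected_model("LASSO", est$subset,
                          cvfit$cvm[cvfit$lambda == lam][1], penalty = lam)
  attr(model, "fit") <- est
  model
}

#' Simulated-annealing kNN descriptor selection
#'
#' For each subset size `D` in `d_min..d_max`, anneals over subsets of
#' exactly `D` descriptors: each step swaps `m_mutate` in-subset descriptors
#' for out-of-subset ones, scores the candidate by the cross-validated kNN
#' error minimised over `k = 1..k_max`, and accepts by the Metropolis rule
#' with the objective change expressed as a percentage of the response
#' variance (`delta = 100 * dMSE / var(y)`), so the published temperature
#' scale is commensurate with the objective.  The overall best
#' `(subset, k)` across all `D` is returned.
#'
#' @param train a `dcv_dataset` with at least `k_max + 2` rows.
#' @param design a `dcv_design`; the split set is shared across all `D`.
#' @param params a `dcv_saknn_params` with `d_max < ncol(train$X)`.
#' @param seed integer seed.
#' @return a `dcv_selected` with `n_neighbors`; the per-`D` annealing
#'   temperatures are attached as attribute `"schedule"`.
#' @export
saknn_select <- function(train, design, params = saknn_params(), seed = 1L) {
  stopifnot(inherits(train, "dcv_dataset"),
            inherits(params, "dcv_saknn_params"))
  p <- ncol(train$X)
  n <- nrow(train$X)
  if (params$d_max >= p) stop("'d_max' must be smaller than the number of predictors")
  stopifnot(n >= params$k_max + 2)
  splits <- make_inner_splits(n, design, derive_seed(seed, 0L))
  vy <- var(train$y)
  temps <- saknn_schedule(params)
  best <- list(obj = Inf, subset = NULL, k = NULL)
  score <- function(subset) {
    per_k <- knn_cv_objective_allk(train, splits, subset, params$k_max)
    kbest <- which.min(per_k)
    list(obj = per_k[kbest], k = kbest)
  }
  for (D in params$d_min:params$d_max) {
    set.seed(derive_seed(seed, D))
    cur <- sort(sample.int(p, D))
    cur_sc <- score(cur)
    if (cur_sc$obj < best$obj) {
      best <- list(obj = cur_sc$obj, subset = cur, k = cur_sc$k)
    }
    for (t in temps) {
      for (step in seq_len(params$n_steps_per_temp)) {
        m <- min(params$m_mutate, D, p - D)
        out_pool <- setdiff(seq_len(p), cur)
        drop_i <- sample(seq_len(D), m)
        add_v <- out_pool[sample.int(length(out_pool), m)]
        cand <- sort(c(cur[-drop_i], add_v))
        cand_sc <- score(cand)
        delta <- 100 * (cand_sc$obj - cur_sc$obj) / vy
        if (delta <= 0 || runif(1) < exp(-delta / t)) {
          cur <- cand
          cur_sc <- cand_sc
          if (cur_sc$obj < best$obj) {
            best <- list(obj = cur_sc$obj, subset = cur, k = cur_sc$k)
          }
        }
      }
    }
  }
  model <- selected_model("KNN", best$subset, best$obj,
                          n_neighbors = as.integer(best$k))
  attr(model, "schedule") <- temps
  model
}
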