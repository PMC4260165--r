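test_that("tabu search equals exhaustive enumeration on a small high-signal instance", {
  d <- toy_signal_data(n = 30, p = 4, n_signal = 2, b_strength = 3,
                       noise_sd = 0.1, seed = 12)
  design <- cv_design("LOO")
  res <- remts_select(d, design, tabu_params(12), "MLR", seed = 1)
  oracle <- exhaustive_best_subset(d, make_inner_splits(30, design), "MLR")
  expect_equal(res$model$subset, oracle$subset)
  expect_equal(res$model$inner_cv_error, oracle$obj, tolerance = 1e-12)
})

test_that("tabu search matches the exhaustive optimum on p = 8 well-separated instances", {
  design <- cv_design("LOO")
  for (seed in c(21, 22, 23)) {
    d <- toy_signal_data(n = 40, p = 8, n_signal = 2, b_strength = 3,
                         noise_sd = 0.3, seed = seed)
    res <- remts_select(d, design, tabu_params(16), "MLR", seed = 1)
    oracle <- exhaustive_best_subset(d, make_inner_splits(40, design), "MLR")
    expect_gte(res$model$inner_cv_error, oracle$obj - 1e-12)
    expect_equal(res$model$inner_cv_error, oracle$obj, tolerance = 1e-10)
    expect_equal(res$model$subset, oracle$subset)
  }
})

test_that("tabu memory never revisits a subset and the trace is consistent", {
  design <- cv_design("LOO")
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rnorm(15 * 6), 15, 6)
    y <- drop(X %*% c(1, 1, 0, 0, 0, 0)) + rnorm(15, sd = 0.8)
    res <- remts_select(dataset(X, y), design, tabu_params(8), "MLR", seed = 1)
    keys <- vapply(res$trace$visited, paste, character(1), collapse = ",")
    expect_equal(anyDuplicated(keys), 0L)
    expect_lte(length(res$trace$visited), 8 + 1)
    expect_equal(res$trace$best_objective,
                 min(res$trace$objective_per_iteration))
  }
})

test_that("pure-noise data under a stringent design stays near the empty model", {
  set.seed(33)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  d <- dataset(X, y)
  design <- cv_design("LMO", 0.8, n_repeats = 30)
  res <- remts_select(d, design, tabu_params(10), "MLR", seed = 2)
  expect_lte(length(res$model$subset), 2)
  # the empty-model objective is the CV estimate of var(y)
  splits <- make_inner_splits(40, design, seed = 2)
  mean_only <- cv_objective(d, splits,
                            list(technique = "MLR", subset = integer(0)))
  expect_lte(res$model$inner_cv_error, mean_only + 1e-12)
  expect_equal(res$model$inner_cv_error, var(y), tolerance = 0.5)
})

test_that("selectors are deterministic given (data, design, params, seed)", {
  pop <- make_population("sim2")
  d <- sample_dataset(pop, n = 40, seed = 44)
  design <- cv_design("LMO", 0.4, n_repeats = 10)
  a <- remts_select(d, design, tabu_params(12), "PCR", seed = 3)
  b <- remts_select(d, design, tabu_params(12), "PCR", seed = 3)
  expect_identical(a$model, b$model)
  expect_identical(a$trace, b$trace)

  la <- lasso_select(d, seed = 3)
  lb <- lasso_select(d, seed = 3)
  expect_identical(la$subset, lb$subset)
  expect_identical(la$penalty, lb$penalty)

  pars <- saknn_params(t_max = 10, t_min = 1, n_steps_per_temp = 3,
                       k_max = 3, d_min = 2, d_max = 3)
  ka <- saknn_select(d, cv_design("LOO"), pars, seed = 3)
  kb <- saknn_select(d, cv_design("LOO"), pars, seed = 3)
  expect_identical(ka$subset, kb$subset)
  expect_identical(ka$n_neighbors, kb$n_neighbors)
})

test_that("tabu-PCR co-optimises the rank within the scoring", {
  pop <- make_population("sim2")
  d <- sample_dataset(pop, seed = 55)
  design <- cv_design("LMO", 0.6, n_repeats = 10)
  res <- remts_select(d, design, tabu_params(12), "PCR", seed = 5)
  m <- res$model
  expect_true(m$rank >= 1 && m$rank <= length(m$subset))
  # the returned error is exactly the rank-minimised objective of that subset
  splits <- make_inner_splits(80, design, seed = 5)
  expect_equal(m$inner_cv_error,
               cv_objective(d, splits,
                            list(technique = "PCR", subset = m$subset)),
               tolerance = 1e-12)
})

test_that("lasso_select behaves sensibly on pure noise and dominant signal", {
  set.seed(66)
  X <- matrix(rnorm(200 * 10), 200, 10)
  noise <- dataset(X, rnorm(200))
  m <- lasso_select(noise, seed = 1)
  expect_lte(length(m$subset), 3)
  expect_equal(m$inner_cv_error, 1, tolerance = 0.25)

  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    Xs <- matrix(rnorm(60 * 8), 60, 8)
    ys <- 3 * Xs[, 4] + rnorm(60, sd = 0.5)
    sel <- lasso_select(dataset(Xs, ys), seed = s)
    if (4 %in% sel$subset) hits <- hits + 1
  }
  expect_gte(hits, 19)

  # k = n boundary: leave-one-out penalty selection (cv.glmnet warns about
  # single-observation folds; that is the point of the boundary case)
  d20 <- toy_signal_data(n = 20, p = 4, seed = 13)
  sel_loo <- suppressWarnings(lasso_select(d20, n_folds = 20, seed = 1))
  expect_true(1 %in% sel_loo$subset)
})

test_that("lasso_select subset size shrinks as noise grows (in expectation)", {
  sizes <- vapply(c(0.5, 5), function(sig) {
    mean(vapply(1:20, function(s) {
      set.seed(s)
      X <- matrix(rnorm(60 * 10), 60, 10)
      y <- drop(X %*% c(1, 1, rep(0, 8))) + rnorm(60, sd = sig)
      length(lasso_select(dataset(X, y), seed = s)$subset)
    }, numeric(1)))
  }, numeric(1))
  expect_lte(sizes[2], sizes[1])
})

test_that("the SA-kNN temperature schedule follows the published cooling", {
  pars <- saknn_params()  # t_max 60, t_min 1e-3, cooling 0.4
  sched <- saknn_schedule(pars)
  # direct loop oracle: smallest m with 60 * 0.4^m < 1e-3
  m <- 0
  while (60 * 0.4^m >= 1e-3) m <- m + 1
  expect_length(sched, m)
  expect_equal(sched[1], 60)
  expect_equal(sched[-1] / sched[-length(sched)],
               rep(0.4, length(sched) - 1), tolerance = 1e-12)
})

test_that("SA-kNN finds a perfectly predictive descriptor", {
  hits <- 0
  pars <- saknn_params(t_max = 10, t_min = 0.1, n_steps_per_temp = 8,
                       k_max = 3, d_min = 1, d_max = 1)
  for (s in 1:20) {
    set.seed(s + 200)
    X <- matrix(rnorm(30 * 6), 30, 6)
    y <- X[, 3]  # descriptor 3 predicts y exactly
    sel <- saknn_select(dataset(X, y), cv_design("LOO"), pars, seed = s)
    if (identical(sel$subset, 3L)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("saknn_select validates its arguments", {
  d <- toy_signal_data(n = 20, p = 4, seed = 14)
  expect_error(saknn_select(d, cv_design("LOO"),
                            saknn_params(d_min = 2, d_max = 4), seed = 1),
               "d_max")
})
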