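test_that("analytic expected coefficients obey Gauss-Markov and the omitted-variable formula", {
  pop <- make_population("sim1")
  # subset containing the support: unbiased OLS
  eb <- expected_coefficients(pop, "MLR", subset = c(3, 7, 14),
                              method = "analytic")
  expect_equal(eb, pop$b, tolerance = 1e-12)

  # scalar omitted-variable case: p = 2, rho = 0.5, b = (1, 1), subset = {1}
  pop2 <- make_population("custom", p = 2, b = c(1, 1), rho = 0.5)
  eb2 <- expected_coefficients(pop2, "MLR", subset = 1, method = "analytic")
  expect_equal(eb2, c(1.5, 0), tolerance = 1e-12)

  expect_error(expected_coefficients(pop, "PCR", subset = 1:3, rank = 2,
                                     method = "analytic"), "MLR")
})

test_that("Monte-Carlo expectations agree with the analytic formula within 3 SE", {
  pop <- make_population("custom", p = 2, b = c(1, 1), rho = 0.5)
  # independent Monte-Carlo oracle with per-draw spread
  n_mc <- 800
  draws <- matrix(NA_real_, n_mc, 2)
  for (i in seq_len(n_mc)) {
    tr <- sample_dataset(pop, n = 80, seed = derive_seed(42, 6L, i))
    draws[i, ] <- fit_mlr(tr, 1)$beta
  }
  se <- apply(draws, 2, sd) / sqrt(n_mc)
  mc <- expected_coefficients(pop, "MLR", subset = 1, method = "monte_carlo",
                              n_mc = n_mc, seed = 42)
  expect_equal(mc, colMeans(draws), tolerance = 1e-12)  # same seeded stream
  analytic <- c(1.5, 0)
  expect_true(all(abs(mc - analytic) <= 3 * pmax(se, 1e-12)))
})

test_that("coefficient decomposition collapses correctly in degenerate cases", {
  pop <- make_population("sim1")
  tab <- expectation_table(pop, method = "analytic")
  eb <- expected_coefficients(pop, "MLR", subset = c(7, 14),
                              method = "analytic")

  fake_record <- function(beta) {
    list(k = 1, selected = selected_model_for_test(c(7L, 14L)), beta = beta,
         pe_k = 0, internal_error_k = 0)
  }
  # every estimate equals its expectation: var = 0, mse = bias
  recs <- list(fake_record(eb), fake_record(eb))
  cd <- coef_decomposition(recs, tab, pop)
  expect_equal(cd[["var_b"]], 0)
  expect_equal(cd[["mse_b"]], cd[["bias_b"]], tolerance = 1e-12)

  # correct specification: expectation equals b, so bias = 0 and mse = var
  shifted <- pop$b + c(rep(0, 6), 0.1, rep(0, 14))
  cd2 <- coef_decomposition(list(fake_record(shifted)), tab, pop)
  expect_equal(cd2[["bias_b"]], 0, tolerance = 1e-24)
  expect_equal(cd2[["mse_b"]], cd2[["var_b"]], tolerance = 1e-12)
})

test_that("mse(b) = bias(b) + var(b) and me identities hold in expectation", {
  pop <- make_population("sim1")
  gaps_b <- numeric(20)
  gaps_me <- numeric(20)
  for (r in 1:20) {
    d <- sample_dataset(pop, seed = 300 + r)
    res <- run_double_cv(d, selector_fixed("MLR", c(7, 14)), cv_design("LOO"),
                         n_test = 8, n_outer = 10, seed = r,
                         population = pop)
    dec <- decompose_dcv(res, d, pop, method = "analytic")
    gaps_b[r] <- dec$mse_b - (dec$bias_b + dec$var_b)
    gaps_me[r] <- dec$me_dcv - (dec$bias_me + dec$var_me)
    # identity by construction, every run
    expect_identical(dec$pe_theo_dcv, dec$me_theo_dcv + pop$sigma2)
  }
  expect_true(within_3se_of_zero(gaps_b))
  expect_true(within_3se_of_zero(gaps_me))
})

test_that("me_decomposition matches hand-unrolled quadratic forms", {
  pop <- make_population("custom", p = 3, b = c(1, 0, 0), rho = 0, n = 12)
  d <- sample_dataset(pop, n = 12, seed = 61)
  res <- run_double_cv(d, selector_fixed("MLR", 1L), cv_design("LOO"),
                       n_test = 2, n_outer = 3, seed = 13, population = pop)
  tab <- expectation_table(pop, method = "analytic")
  md <- me_decomposition(res$records, tab, pop, res$partitions, d)
  # with rho = 0 and subset {1} containing the support, E beta = b
  me_hand <- mean(vapply(1:3, function(k) {
    Xt <- d$X[res$partitions[[k]]$test_idx, , drop = FALSE]
    db <- res$records[[k]]$beta - pop$b
    sum((Xt %*% db)^2) / nrow(Xt)
  }, numeric(1)))
  expect_equal(md[["me_dcv"]], me_hand, tolerance = 1e-12)
  expect_equal(md[["bias_me"]], 0, tolerance = 1e-20)
  expect_equal(md[["var_me"]], me_hand, tolerance = 1e-12)
})

test_that("me_theo evaluates the population quadratic form", {
  pop <- make_population("sim1")
  expect_equal(me_theo(pop$b, pop), 0)

  popI <- make_population("custom", p = 4, b = rep(0, 4), rho = 0)
  expect_equal(me_theo(c(1, 0, 0, 0), popI), 1)

  # sim2 zero model: b'Vb by an explicit double-loop oracle
  pop2 <- make_population("sim2")
  acc <- 0
  for (i in 1:21) for (j in 1:21) acc <- acc + pop2$b[i] * pop2$V[i, j] * pop2$b[j]
  expect_equal(me_theo(rep(0, 21), pop2), acc, tolerance = 1e-12)
  expect_equal(acc, 2.5079, tolerance = 1e-4)
})

test_that("me_theo is consistent with empirical model error on fresh test data", {
  pop <- make_population("sim2")
  beta <- pop$b + c(rep(0, 5), 0.3, rep(0, 15))
  target <- me_theo(beta, pop)
  big <- sample_dataset(pop, n = 1e5, seed = 71)
  emp <- mean((big$X %*% (beta - pop$b))^2)
  expect_equal(emp, target, tolerance = 0.02)
})

test_that("bias of the correctly specified MLR vanishes under Monte-Carlo expectations", {
  pop <- make_population("sim1")
  tab <- expectation_table(pop, method = "monte_carlo", n_mc = 500, seed = 5)
  recs <- lapply(1:5, function(k) {
    d <- sample_dataset(pop, seed = 400 + k)
    list(k = k, selected = selected_model_for_test(c(7L, 14L)),
         beta = fit_mlr(d, c(7, 14))$beta, pe_k = 0, internal_error_k = 0)
  })
  cd <- coef_decomposition(recs, tab, pop)
  expect_lt(abs(cd[["bias_b"]]), 0.02)
})

test_that("rel_dev and study_average follow their definitions", {
  expect_equal(rel_dev(2, 2), 0)
  expect_equal(rel_dev(1.05 * 2, 2), 5)
  expect_equal(rel_dev(0.95 * 2, 2), -5)
  expect_error(rel_dev(1, 0), "positive")

  one <- study_average(data.frame(pe = 1.3))
  expect_equal(one$mean, 1.3)
  expect_equal(one$sd, 0)

  const <- study_average(data.frame(pe = rep(2.5, 10)))
  expect_equal(const$mean, 2.5)
  expect_equal(const$sd, 0)

  set.seed(81)
  z <- study_average(data.frame(x = rnorm(200)))
  expect_lt(abs(z$mean), 3 / sqrt(200))
  expect_equal(z$se, z$sd / sqrt(200))
})
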