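test_that("fit_mlr recovers exact linear data and matches the normal equations", {
  # exact interpolation: t = 2 + 3 x1 - x2, no noise
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  t <- 2 + 3 * X[, 1] - X[, 2]
  tab <- analyte_table(paste0("a", 1:20), X, t + 10)  # shift keeps t > 0
  m <- fit_mlr(tab)
  expect_equal(unname(c(m$intercept, m$coefficients)), c(12, 3, -1),
               tolerance = 1e-10)
  expect_equal(unname(predict(m, tab)), unname(tab$t_obs), tolerance = 1e-10)

  # random designs vs the (X'X)^-1 X'y oracle
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(8:50, 1); K <- sample(1:4, 1)
    Xr <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, paste0("d", 1:K)))
    tabr <- analyte_table(paste0("r", 1:n), Xr, runif(n, 1, 30))
    mr <- fit_mlr(tabr)
    expect_equal(unname(c(mr$intercept, mr$coefficients)),
                 unname(oracle_ols(Xr, tabr$t_obs)), tolerance = 1e-8)
  }
})

test_that("fit_mlr rejects rank-deficient and undersized designs", {
  X <- cbind(d1 = 1:10, d2 = 2 * (1:10))  # collinear
  tab <- analyte_table(paste0("a", 1:10), X, 1:10 + 0.5)
  expect_error(fit_mlr(tab), "singular|collinear")
  tab2 <- random_table(n = 4, K = 3, seed = 1)
  expect_error(fit_mlr(tab2, 1:3), "K \\+ 2")
})

test_that("predict is the affine map over the named descriptor columns", {
  tab <- random_table(n = 10, K = 3, seed = 5)
  m0 <- qsrr_model(5, c(d1 = 0, d2 = 0, d3 = 0))
  expect_equal(unname(predict(m0, tab)), rep(5, 10))
  m1 <- qsrr_model(0, c(d1 = 1, d2 = 0, d3 = 0))
  expect_equal(unname(predict(m1, tab)), unname(tab$X[, "d1"]))
  m_bad <- qsrr_model(0, c(other = 1))
  expect_error(predict(m_bad, tab), "other")
})

test_that("percent_rmse_tr matches hand-computed relative RMSE values", {
  expect_equal(percent_rmse_tr(c(1, 2, 4), c(1.1, 1.8, 4.4)), 10.0,
               tolerance = 1e-12)
  expect_equal(percent_rmse_tr(c(5.1, 5.2), c(5.0, 5.1)), 1.942022139,
               tolerance = 1e-8)
  expect_equal(percent_rmse_tr(c(3, 7), c(3, 7)), 0)
  # literal printed form: signed mean relative error, no square/root
  expect_equal(percent_rmse_tr(c(1, 2), c(1.1, 1.8), variant = "literal_eq6"),
               100 * mean(c(0.1, -0.1)), tolerance = 1e-12)
  expect_error(percent_rmse_tr(c(1, 2), c(1)), "mismatch")
  expect_error(percent_rmse_tr(c(0, 2), c(1, 2)), "> 0")
})

test_that("percent_rmse_tr strictly increases when one relative error grows", {
  obs <- c(2, 4, 8); pred <- c(2.2, 3.9, 8.1)
  base <- percent_rmse_tr(obs, pred)
  worse <- pred; worse[2] <- 3.5
  expect_gt(percent_rmse_tr(obs, worse), base)
})

test_that("elution_ranks is a stable ascending ranking", {
  expect_equal(elution_ranks(c(5.1, 5.2)), c(1L, 2L))
  expect_equal(elution_ranks(c(3.0, 1.0, 2.0)), c(3L, 1L, 2L))
  expect_equal(elution_ranks(1:6), 1:6)
  expect_equal(elution_ranks(c(2, 2, 1)), c(2L, 3L, 1L))  # tie: row order
  for (seed in 1:10) {
    set.seed(seed)
    t <- sample(c(runif(8), runif(4)), 12, replace = TRUE)  # with ties
    r <- elution_ranks(t)
    expect_setequal(r, 1:12)
  }
})

test_that("percent_rmse_order matches hand-computed rank-error values", {
  expect_equal(percent_rmse_order(1:5, 1:5), 0)
  expect_equal(percent_rmse_order(1:2, 2:1), 79.05694150, tolerance = 1e-8)
  expect_equal(percent_rmse_order(1:3, c(1, 3, 2)), 34.69443332,
               tolerance = 1e-8)
  expect_equal(percent_rmse_order(1:4, 4:1), 157.5088181, tolerance = 1e-7)
  expect_error(percent_rmse_order(1:3, c(1, 1, 2)), "permutation")
})

test_that("order error is invariant under strictly monotone transforms of predictions", {
  tab <- random_table(n = 25, seed = 7)
  m <- fit_mlr(tab)
  t_pred <- predict(m, tab)
  r_obs <- elution_ranks(tab$t_obs)
  f2 <- percent_rmse_order(r_obs, elution_ranks(t_pred))
  for (g in list(function(x) 2 * x + 3, exp, function(x) x^3))
    expect_equal(percent_rmse_order(r_obs, elution_ranks(g(t_pred))), f2)
})

test_that("evaluate_model computes subset-local objectives", {
  gen <- generate_linear_dataset(generator_spec(30, 2, c(10, 2, -1), seed = 9))
  m <- fit_mlr(gen$table)
  expect_equal(unname(evaluate_model(m, gen$table)), c(0, 0), tolerance = 1e-8)
  # ranks are re-derived within the subset: a subset evaluation must not
  # depend on analytes outside it
  noisy <- generate_linear_dataset(
    generator_spec(30, 2, c(10, 2, -1), noise_sd = 1, seed = 9))
  mn <- fit_mlr(noisy$table)
  idx <- 11:30
  sub <- subset_table(noisy$table, idx)
  expect_equal(unname(evaluate_model(mn, noisy$table, idx)),
               unname(evaluate_model(mn, sub)), tolerance = 1e-12)
})
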