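test_that("critical leverage arithmetic follows both conventions", {
  expect_equal(critical_leverage(4, 43), 9 / 43, tolerance = 1e-12)
  expect_equal(round(critical_leverage(4, 43), 4), 0.2093)
  expect_equal(round(critical_leverage(4, 43, "conventional_k_plus_1"), 4),
               0.3488)
  expect_warning(h0 <- critical_leverage(1, 10), "h\\* = 0")
  expect_equal(h0, 0)
  expect_error(critical_leverage(0, 10), "positive")
})

test_that("leverages agree with the explicit hat-matrix oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(6:50, 1); K <- sample(1:4, 1)
    X <- cbind(1, matrix(rnorm(n * K), n, K))
    h <- leverages(X)
    expect_equal(h, oracle_leverage(X), tolerance = 1e-8)
    expect_equal(sum(h), K + 1, tolerance = 1e-8)  # hat-matrix trace
    expect_true(all(h > 0 & h <= 1))
  }
  # query at the training centroid has leverage 1/N
  set.seed(99)
  Xtr <- cbind(1, matrix(rnorm(30), 15, 2))
  centroid <- colMeans(Xtr)
  expect_equal(leverages(Xtr, matrix(centroid, 1)), 1 / 15, tolerance = 1e-10)
  expect_error(leverages(cbind(1, rep(2, 5))), "singular")
})

test_that("standardized residuals scale correctly", {
  expect_equal(standardized_residuals(c(-1, 1)), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  r <- c(-2.3, 0.4, 1.1, 0.8)
  expect_equal(standardized_residuals(10 * r), standardized_residuals(r) *
                 10 / 10)  # scale invariance
  expect_warning(z <- standardized_residuals(rep(0, 4)), "zero")
  expect_equal(z, rep(0, 4))
})

test_that("williams_report flags partition the analytes correctly", {
  # noise-free: everything inside (residuals all ~0 after sd guard)
  gen <- generate_linear_dataset(
    generator_spec(30, 3, c(20, 3, 1, -2), noise_sd = 0.3, seed = 13))
  sp <- kennard_stone_split(gen$table, 0.7)
  m <- fit_mlr(gen$table, sp$train_indices)
  rep <- williams_report(m, gen$table, sp)
  expect_equal(sum(rep$counts), gen$table$n)
  expect_equal(rep$K_used, 4L)
  expect_equal(rep$h_star, 3 * 3 / rep$N_used)
  # training leverages sum to the parameter count
  htr <- rep$analytes$leverage[rep$analytes$set_label == "train"]
  expect_equal(sum(htr), 4, tolerance = 1e-8)
  # flag definitions hold row by row
  with(rep$analytes, {
    expect_true(all((flag == "x_outlier") ==
                      (leverage > rep$h_star & abs(std_residual) <= 3)))
    expect_true(all((flag == "y_outlier") ==
                      (abs(std_residual) > 3 & leverage <= rep$h_star)))
  })
})

test_that("a far-away test analyte is flagged as a structural (x) outlier", {
  gen <- generate_linear_dataset(
    generator_spec(30, 3, c(20, 3, 1, -2), noise_sd = 0.2, seed = 14))
  tab <- gen$table
  X2 <- tab$X
  X2[30, ] <- X2[30, ] + 100  # push one analyte far outside the cloud
  sp <- kennard_stone_split(subset_table(tab, 1:29), 0.7)
  m <- fit_mlr(tab, sp$train_indices)
  t2 <- tab$t_obs
  t2[30] <- drop(m$intercept + X2[30, ] %*% m$coefficients)  # on-model response
  tab2 <- analyte_table(tab$ids, X2, t2)
  sp$test_indices <- c(sp$test_indices, 30L)
  rep <- williams_report(m, tab2, sp)
  expect_equal(rep$analytes$flag[30], "x_outlier")
})
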