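test_that("srd_value matches hand computations and is a symmetric distance", {
  expect_equal(srd_value(1:5, 1:5), 0)
  expect_equal(srd_value(c(2, 1, 4, 3), 1:4), 4)
  expect_equal(srd_value(c(2, 1, 4, 3), 1:4, mode = "squared"), 4)
  expect_equal(srd_value(4:1, 1:4), 8)
  expect_equal(srd_value(4:1, 1:4, mode = "squared"), 20)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:10, 1)
    a <- sample(n); b <- sample(n)
    expect_equal(srd_value(a, b), srd_value(b, a))
    expect_lte(srd_value(a, b), srd_max(n))
    expect_equal(srd_value(a, b) == 0, identical(a, b))
  }
  expect_error(srd_value(c(1, 1, 2), 1:3), "permutation")
})

test_that("srd_max equals exhaustive maxima over all permutations (n <= 6)", {
  for (n in 2:6) {
    perms <- qsrrmoo:::all_permutations(n)
    ref <- seq_len(n)
    abs_max <- max(apply(perms, 1, function(p) sum(abs(p - ref))))
    sq_max <- max(apply(perms, 1, function(p) sum((p - ref)^2)))
    expect_equal(srd_max(n, "absolute"), abs_max)
    expect_equal(srd_max(n, "squared"), sq_max)
  }
  expect_equal(srd_max(4), 8)
  expect_equal(srd_max(5), 12)
  expect_error(srd_max(1), "n >= 2")
})

test_that("rank_models normalizes and orders models by closeness to the reference", {
  ref <- 1:4
  orders <- list(m1 = c(2, 1, 4, 3), m2 = 4:1, m3 = 1:4)
  rep <- rank_models(orders, ref)
  expect_equal(rep$models$model_label, c("m3", "m1", "m2"))
  expect_equal(rep$models$srd_percent, c(0, 50, 100))
  crnn <- crnn_distribution(20, n_draws = 2000, seed = 2)
  rep2 <- rank_models(list(perfect = 1:20, random = sample(20)), 1:20,
                      crnn = crnn)
  expect_true(rep2$models$significant_vs_random[rep2$models$model_label == "perfect"])
})

test_that("exhaustive enumeration gives the known small-n distributions", {
  d2 <- exhaustive_crnn(2)
  expect_equal(d2$raw, c(0, 2))
  expect_equal(d2$percent, c(0, 100))
  d3 <- exhaustive_crnn(3)
  expect_equal(d3$raw, c(0, 2, 2, 4, 4, 4))
  for (n in c(4, 6)) {
    d <- exhaustive_crnn(n)
    expect_length(d$raw, factorial(n))
    expect_equal(d$mean_raw, (n^2 - 1) / 3, tolerance = 1e-12)  # footrule mean
  }
  expect_error(exhaustive_crnn(9), "2\\.\\.8")
})

test_that("simulated CRNN distribution converges to the exact one at n = 7", {
  # the SRD distribution is discrete: bracket each simulated quantile by the
  # exact inverse-CDF quantiles at p +/- 3 binomial standard errors
  exact <- exhaustive_crnn(7)
  sim <- crnn_distribution(7, n_draws = 40000, seed = 4)
  ps <- c(0.05, 0.5, 0.95)
  eps <- 3 * sqrt(ps * (1 - ps) / 40000)
  lo <- quantile(exact$percent, pmax(ps - eps, 0), type = 1, names = FALSE)
  hi <- quantile(exact$percent, pmin(ps + eps, 1), type = 1, names = FALSE)
  sim_q <- c(sim$xx1, sim$median, sim$xx9)
  expect_true(all(sim_q >= lo - 1e-9 & sim_q <= hi + 1e-9))
  expect_true(sim$xx1 <= sim$median && sim$median <= sim$xx9)
})

test_that("CRNN for 98 objects brackets the footrule null statistics", {
  sim <- crnn_distribution(98, n_draws = 20000, seed = 6)
  expect_gt(sim$median, 65); expect_lt(sim$median, 68)
  expect_gt(sim$xx1, 58); expect_lt(sim$xx1, 61)
  expect_gt(sim$xx9, 72); expect_lt(sim$xx9, 75)
  # squared mode centres near 50% instead
  sim_sq <- crnn_distribution(98, n_draws = 5000, seed = 6, mode = "squared")
  expect_gt(sim_sq$median, 45); expect_lt(sim_sq$median, 55)
  # determinism
  sim2 <- crnn_distribution(98, n_draws = 20000, seed = 6)
  expect_identical(sim$median, sim2$median)
})
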