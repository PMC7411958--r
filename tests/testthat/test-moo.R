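test_that("pareto_filter equals the brute-force dominance oracle", {
  expect_equal(pareto_filter(1, 1), 1L)
  expect_equal(pareto_filter(c(0, 1, 1), c(1, 0, 1)), c(1L, 2L))
  for (seed in 1:5) {
    set.seed(seed)
    f1 <- round(runif(100), 2)  # rounding forces some exact duplicates
    f2 <- round(runif(100), 2)
    expect_equal(pareto_filter(f1, f2), oracle_pareto(f1, f2))
  }
  expect_length(pareto_filter(numeric(0), numeric(0)), 0)
})

test_that("knee_point matches brute-force distance minimization", {
  fr <- generate_front_fixture("single_point")
  expect_equal(knee_point(fr), 1L)
  frL <- generate_front_fixture("L_shaped")
  expect_equal(knee_point(frL), 2L)  # (0.1, 0.1) vs corners at distance 1
  for (seed in 1:8) {
    set.seed(seed)
    m <- sample(2:50, 1)
    f1 <- sort(runif(m)); f2 <- sort(runif(m), decreasing = TRUE)
    keep <- pareto_filter(f1, f2)
    fr2 <- list(f1 = f1[keep], f2 = f2[keep])
    expect_equal(knee_point(fr2), oracle_knee(fr2$f1, fr2$f2))
  }
})

test_that("select_solution applies the retention-loss budget with argmin-f1 fallback", {
  # arithmetic on a control/MOO pair shaped like a published column result
  fr <- generate_front_fixture("L_shaped")
  fr$control <- c(f1 = 8.57, f2 = 59.07)
  fr$f1 <- c(9.33, 10.21); fr$f2 <- c(42.04, 40.0)
  fr$coefficients <- matrix(0, 2, 2,
                            dimnames = list(NULL, c("(Intercept)", "d1")))
  sel <- select_solution(fr, 10)
  expect_equal(sel$selected_index, 1L)  # +8.87% feasible, +19.1% is not

  # all infeasible -> lowest f1
  sel0 <- select_solution(fr, 1)
  expect_equal(sel0$selected_index, 1L)
  fr$f1 <- c(20, 30); fr$f2 <- c(5, 1)
  expect_equal(select_solution(fr, 10)$selected_index, 1L)
})

test_that("compare_to_control reproduces published-style deltas", {
  expect_equal(unname(compare_to_control(c(8.57, 59.07), c(8.57, 59.07))),
               c(0, 0))
  expect_equal(unname(compare_to_control(c(8.57, 59.07), c(9.33, 42.04))),
               c(8.868144691, -28.83020146), tolerance = 1e-8)
  expect_equal(unname(compare_to_control(c(39.28, 195.82), c(40.85, 31.08))),
               c(3.99694501, -84.12828107), tolerance = 1e-8)
  expect_error(compare_to_control(c(0, 1), c(1, 1)), "non-zero")
})

test_that("optimize_moo finds the exact solution on noise-free data and is elitist", {
  gen <- generate_linear_dataset(
    generator_spec(40, 2, c(15, 4, -2), noise_sd = 0, seed = 21))
  tab <- gen$table
  m <- fit_mlr(tab)
  fr <- optimize_moo(tab, seq_len(tab$n), m,
                     ga_params(population_size = 40, generations = 30, seed = 5))
  expect_lte(min(fr$f1), 1e-6)
  expect_equal(min(fr$f2), 0)
  expect_lte(min(fr$f2), fr$control[["f2"]])
  expect_lte(min(fr$f1), fr$control[["f1"]] + 1e-9)
})

test_that("optimize_moo is reproducible and returns a clean Pareto front", {
  gen <- generate_linear_dataset(preset_cs1_like(seed = 31))
  tab <- gen$table
  sp <- kennard_stone_split(tab, 0.7)
  m <- fit_mlr(tab, sp$train_indices)
  p <- ga_params(population_size = 30, generations = 25, seed = 17)
  fr1 <- optimize_moo(tab, sp$train_indices, m, p)
  fr2 <- optimize_moo(tab, sp$train_indices, m, p)
  expect_identical(fr1$f1, fr2$f1)
  expect_identical(fr1$coefficients, fr2$coefficients)

  # front passes pareto_filter unchanged, sorted ascending in f1 with f2
  # strictly decreasing
  expect_equal(pareto_filter(fr1$f1, fr1$f2), seq_along(fr1$f1))
  if (length(fr1$f1) > 1) {
    expect_true(all(diff(fr1$f1) > 0))
    expect_true(all(diff(fr1$f2) < 0))
  }
  # elitism relative to the seeded control
  expect_lte(min(fr1$f2), fr1$control[["f2"]])
  expect_lte(min(fr1$f1), fr1$control[["f1"]] + 1e-9)
})

test_that("front_model round-trips coefficients and front_as_df flags knee/selected", {
  gen <- generate_linear_dataset(preset_cs1_like(seed = 41))
  sp <- kennard_stone_split(gen$table, 0.7)
  m <- fit_mlr(gen$table, sp$train_indices)
  fr <- optimize_moo(gen$table, sp$train_indices, m,
                     ga_params(population_size = 20, generations = 10, seed = 3))
  fr <- select_solution(fr, 10)
  sel <- front_model(fr)
  ev <- evaluate_model(sel, gen$table, sp$train_indices)
  expect_equal(unname(ev[1]), fr$f1[fr$selected_index], tolerance = 1e-9)
  df <- front_as_df(fr)
  expect_equal(which(df$is_knee), fr$knee_index)
  expect_equal(which(df$is_selected), fr$selected_index)
  expect_equal(nrow(df), length(fr$f1))
})
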