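test_that("Monte Carlo recovers the geometric closed form", {
  ch <- augment_chain(matrix(1), alpha = 0.5)  # mean time 1 / 0.5 = 2
  mc <- simulate_absorption_times(ch, n = 1e5, seed = 101)
  expect_lt(abs(mc$mean - 2), 3 * mc$se)
  expect_identical(mc$n_censored, 0L)
})

test_that("immediate absorption yields unit hitting times", {
  P <- random_stochastic(3, seed = 1)
  ch <- augment_chain(P, rep(1 - 1e-6, 3))
  mc <- simulate_absorption_times(ch, n = 500, seed = 2)
  expect_true(all(mc$times == 1))
})

test_that("Monte Carlo agrees with the matrix solution on a 6-state chain", {
  ch <- random_absorbing(6, seed = 42, lo = 0.05, hi = 0.25)
  p0 <- c(0.3, 0.2, 0.1, 0.1, 0.2, 0.1)
  sol <- fundamental_solution(ch, p0 = p0)
  mc <- simulate_absorption_times(ch, n = 1e5, p0 = p0, seed = 77)
  expect_lt(abs(mc$mean - sol$expected_time_p0), 3 * mc$se)
})

test_that("censoring is accounted for and total replicates conserved", {
  ch <- augment_chain(matrix(1), alpha = 0.05)  # mean 20 steps
  expect_warning(mc <- simulate_absorption_times(ch, n = 2000, max_steps = 5,
                                                 seed = 3),
                 "censored")
  expect_identical(length(mc$times) + mc$n_censored, 2000L)
  expect_gt(mc$n_censored, 0L)
  expect_error(
    suppressWarnings(simulate_absorption_times(ch, n = 50, max_steps = 1,
                                               seed = 4)),
    NA)  # max_steps 1 still absorbs ~5% of replicates
  ch_slow <- augment_chain(matrix(1), alpha = 1e-6)
  expect_error(simulate_absorption_times(ch_slow, n = 20, max_steps = 2,
                                         seed = 5),
               "all replicates censored")
})

test_that("the generator is deterministic and respects the budget", {
  cfg <- synthetic_cow_config()
  a <- generate_behavior_series(cfg, seed = 9)
  b <- generate_behavior_series(cfg, seed = 9)
  expect_identical(a$values, b$values)
  expect_identical(a$event_hour, b$event_hour)
  expect_true(all(a$values == round(a$values)))   # integer minutes
  expect_true(all(rowSums(a$values) <= 60))
  expect_identical(nrow(a$values), 240L)
})

test_that("zero drift with infinite dispersion reproduces the baseline", {
  cfg <- synthetic_cow_config(restlessness_drift = rep(0, 6),
                              dispersion = Inf, event_hazard = 0)
  s <- generate_behavior_series(cfg, seed = 1)
  # the default baseline is integer-valued, so every hour equals it exactly
  for (j in 1:6)
    expect_equal(unname(s$values[, j]),
                 rep(unname(cfg$baseline_budget[j]), 240))
  expect_null(s$event_hour)
})

test_that("a unit hazard forces the event at that hour", {
  hz <- numeric(48); hz[24] <- 1
  cfg <- synthetic_cow_config(horizon_hours = 48, event_hazard = hz)
  for (seed in 1:5)
    expect_identical(generate_behavior_series(cfg, seed = seed)$event_hour,
                     24L)
})

test_that("restlessness drift depresses lying rest by the final hour", {
  cfg <- synthetic_cow_config(event_hazard = 0)
  last_minus_first <- vapply(1:200, function(seed) {
    v <- generate_behavior_series(cfg, seed = seed)$values[, "lying_rest"]
    v[240] - v[1]
  }, numeric(1))
  bt <- binom.test(sum(last_minus_first < 0),
                   sum(last_minus_first != 0), alternative = "greater")
  expect_lt(bt$p.value, 1e-6)
  expect_lt(mean(last_minus_first), 0)
})

test_that("the end-to-end fixture is reproducible and internally consistent", {
  cfg <- synthetic_cow_config()
  f1 <- suppressWarnings(pipeline_fixture(cfg, k_sd = 1, seed = 3))
  f2 <- suppressWarnings(pipeline_fixture(cfg, k_sd = 1, seed = 3))
  expect_identical(f1$series$values, f2$series$values)
  expect_identical(f1$states$states, f2$states$states)
  expect_equal(f1$solution$N, f2$solution$N)
  expect_equal(unname(rowSums(f1$chain$P)), rep(1, 6), tolerance = 1e-12)
  expect_true(is.finite(f1$solution$expected_time_total))
  expect_gt(f1$solution$expected_time_total, 0)
})

test_that("a uniformly higher event hazard shortens the expected time", {
  slow <- synthetic_cow_config(event_hazard = 0.002)
  fast <- synthetic_cow_config(event_hazard = 0.05)
  fit_slow <- suppressWarnings(
    calving_chain(generate_cohort(slow, n = 10, seed = 11)))
  fit_fast <- suppressWarnings(
    calving_chain(generate_cohort(fast, n = 10, seed = 11)))
  expect_lt(fit_fast$solution$expected_time_total,
            fit_slow$solution$expected_time_total)
})
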