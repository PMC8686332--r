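test_that("specific growth rate follows the ln-ratio formula", {
  expect_equal(specific_growth_rate(0.1, 0.2, 0, 2), log(2) / 2)
  expect_equal(specific_growth_rate(0.8, 0.8, 4, 6), 0)
  expect_error(specific_growth_rate(0, 0.2, 0, 2), "positive")
  expect_error(specific_growth_rate(0.1, 0.2, 2, 2), "greater")

  # invariant to OD rescaling
  expect_equal(specific_growth_rate(0.1, 0.35, 1, 3),
               specific_growth_rate(0.1 * 7, 0.35 * 7, 1, 3))

  # exact exponential: every point pair returns the true rate
  tt <- seq(0, 12, by = 2)
  od <- 0.05 * exp(0.4 * tt)
  for (i in seq_len(length(tt) - 1)) {
    expect_equal(specific_growth_rate(od[i], od[i + 1], tt[i], tt[i + 1]), 0.4)
  }
})

test_that("maximum growth rate estimators recover a noiseless logistic rate", {
  g <- gen_growth_curve(seed = 1, k = 0.4, noise_sd = 0)
  for (m in c("pairwise_max", "regression")) {
    est <- max_growth_rate(g$curve, method = m)
    expect_lt(abs(est$k - 0.4) / 0.4, 0.05)
  }
  est <- max_growth_rate(g$curve, method = "regression")
  expect_gt(est$r2, 0.99)

  # monotone decline gives a negative rate
  dec <- growth_curve(c(0, 2, 4), c(1, 0.5, 0.25))
  expect_lt(max_growth_rate(dec)$k, 0)

  # two-point curve degenerates to the pairwise formula
  two <- growth_curve(c(0, 2), c(0.1, 0.2))
  expect_equal(max_growth_rate(two)$k, specific_growth_rate(0.1, 0.2, 0, 2))

  expect_error(growth_curve(c(0, 2), c(0, 0)) |> max_growth_rate(),
               "non-positive")
})

test_that("stationary onset is the first crossing of the OD threshold", {
  inc <- growth_curve(c(0, 2, 4, 6), c(1, 5, 9.6, 10))
  expect_equal(stationary_onset(inc), 4)  # 9.6 >= 0.95 * 10
  flat <- growth_curve(c(0, 2, 4), c(2, 2, 2))
  expect_equal(stationary_onset(flat), 0)

  g <- gen_growth_curve(seed = 5, noise_sd = 0)
  expect_lt(abs(stationary_onset(g$curve) - g$truth$t_stationary), 2)
})

test_that("PHA titer arithmetic reproduces printed productivity rows", {
  expect_equal(as.numeric(pha_titer(3.4, c(`3HB` = 48, `3HV` = 14))), 2.1)
  expect_equal(as.numeric(pha_titer(4.4, c(`3HB` = 59, `3HV` = 26))), 3.7)
  expect_equal(as.numeric(pha_titer(5.0, c(0, 0))), 0)
  expect_equal(attr(pha_titer(3.4, c(48, 14)), "exact"), 3.4 * 0.62)

  expect_error(pha_titer(-1, 50), ">= 0")
  expect_error(pha_titer(2, -5), ">= 0")

  # linear in CDW, additive over fractions (on the unrounded value)
  e1 <- attr(pha_titer(2.0, c(30, 10)), "exact")
  expect_equal(attr(pha_titer(4.0, c(30, 10)), "exact"), 2 * e1)
  expect_equal(e1, attr(pha_titer(2.0, 30), "exact") +
                 attr(pha_titer(2.0, 10), "exact"))
})

test_that("rounding is half away from zero at one decimal", {
  vals <- c(2.108, 3.74, 2.379, 1.104, 0.63, 0.3861, 0.65, 0.868)
  expect_equal(vapply(vals, function(v) as.numeric(pha_titer(v, 100)), numeric(1)),
               c(2.1, 3.7, 2.4, 1.1, 0.6, 0.4, 0.7, 0.9))
  expect_equal(as.numeric(pha_titer(1, 25)), 0.3)  # 0.25 rounds up, not to even
})

test_that("dispersion reports population SD and CV", {
  d <- dispersion(c(2, 4))
  expect_equal(d$mean, 3)
  expect_equal(d$population_sd, 1)
  expect_equal(d$cv, 1 / 3)
  expect_equal(dispersion(5)$population_sd, 0)
  expect_error(dispersion(numeric(0)), "no values")

  set.seed(171)
  draws <- rnorm(1000, mean = 0, sd = 2)
  expect_lt(abs(dispersion(draws)$population_sd - 2), 0.15)
  expect_true(is.na(dispersion(c(-1, 1))$cv))
})
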