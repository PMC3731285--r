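# Kaplan-Meier, Weibull and Cox estimation against hand-computed and
# brute-force oracles.

test_that("KM with no events is flat at 1", {
  km <- km_estimate(c(5, 10), c(FALSE, FALSE))
  expect_length(km$event_times, 0)
  expect_equal(km_survival_at(km, c(0, 7, 100)), c(1, 1, 1))
})

test_that("KM reproduces the hand product-limit calculation", {
  km <- km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(km$event_times, c(1, 2, 4))
  expect_equal(km$survival, c(0.75, 0.50, 0.00))
  expect_true(all(km$ci_low <= km$survival + 1e-12 &
                  km$survival <= km$ci_high + 1e-12))
})

test_that("KM on uncensored data equals the empirical survival function", {
  set.seed(1)
  for (rep in 1:5) {
    t <- sample(1:30, 40, replace = TRUE)
    km <- km_estimate(t, rep(TRUE, 40))
    for (d in c(0, 5, 15, 40))
      expect_equal(km_survival_at(km, d), mean(t > d))
  }
})

test_that("KM input validation", {
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "negative")
  expect_error(km_estimate(c(1, 2), TRUE), "lengths differ")
})

test_that("exponential fit equals its closed form (mean survival time)", {
  f <- fit_weibull(c(2, 4, 6), c(TRUE, TRUE, TRUE), fix_shape = 1)
  expect_equal(f$scale, 4.0, tolerance = 1e-9)
  expect_equal(f$shape, 1)
  # censoring: total time / total events
  f2 <- fit_weibull(c(2, 4, 6, 8), c(TRUE, TRUE, FALSE, TRUE), fix_shape = 1)
  expect_equal(f2$scale, 20 / 3, tolerance = 1e-9)
})

test_that("Weibull MLE recovers simulated parameters and matches a grid-search oracle", {
  set.seed(99)
  t <- rweibull(5000, shape = 1.3, scale = 400)
  f <- fit_weibull(t, rep(TRUE, 5000))
  se <- sqrt(diag(f$covariance))
  expect_lt(abs(log(f$shape) - log(1.3)), 3 * se[["log_shape"]])
  expect_lt(abs(log(f$scale) - log(400)), 3 * se[["log_scale"]])
  grid <- weib_grid_mle(t, rep(TRUE, 5000), k_range = c(0.8, 2),
                        l_range = c(200, 800))
  expect_lt(abs(f$shape - grid[["shape"]]), 1e-3)
  expect_lt(abs(f$scale - grid[["scale"]]), 1e-2)   # scale is O(400)
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(fit_weibull(c(1, 2, 3), c(FALSE, FALSE, FALSE)), "cannot fit")
  expect_error(fit_weibull(rep(5, 10), rep(TRUE, 10)), "non-convergence")
})

test_that("daily transition probabilities follow the Weibull survival ratio", {
  f_exp <- fit_weibull(rweibull(500, 1, 100), rep(TRUE, 500), fix_shape = 1)
  f_exp$scale <- 100   # exact parameter for the closed-form check
  p <- daily_transition_prob(f_exp, 0:10)
  expect_equal(p, rep(1 - exp(-0.01), 11), tolerance = 1e-12)

  f <- f_exp; f$family <- "weibull"; f$shape <- 2; f$scale <- 10
  expect_equal(daily_transition_prob(f, 3), 1 - exp(-0.07), tolerance = 1e-12)

  # telescoping identity over the first 90 days
  f$shape <- 1.37; f$scale <- 55
  p90 <- daily_transition_prob(f, 0:89)
  expect_true(all(p90 >= 0 & p90 <= 1))
  expect_equal(prod(1 - p90), fit_survival(f, 90) / fit_survival(f, 0),
               tolerance = 1e-12)
})

test_that("Weibull with shape fixed at 1 matches the exponential closed form", {
  set.seed(3)
  t <- rexp(200, rate = 1 / 30)
  e <- t < 60; t <- pmin(t, 60)
  f <- fit_weibull(t, e, fix_shape = 1)
  expect_equal(f$scale, sum(t) / sum(e), tolerance = 1e-9)
})

test_that("Cox fit is zero under mirror-image groups", {
  f <- fit_cox(c(1, 3, 1, 3), c(TRUE, TRUE, TRUE, TRUE), c(0, 0, 1, 1))
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  expect_equal(unname(f$hazard_ratio), 1, tolerance = 1e-8)
})

test_that("Cox estimate maximizes the written-out Breslow partial likelihood", {
  t <- c(2, 5, 7, 11, 13, 17)
  e <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  x <- c(1, 0, 1, 0, 1, 0)
  f <- fit_cox(t, e, x)
  brute <- stats::optimize(function(b) -cox_partial_loglik(b, t, e, x),
                           c(-5, 5), tol = 1e-10)$minimum
  expect_lt(abs(unname(f$coefficients) - brute), 1e-6)
  expect_true(f$ci_low <= f$hazard_ratio & f$hazard_ratio <= f$ci_high)
})

test_that("Cox estimate is invariant to monotone time rescaling and group relabeling", {
  sv <- register_surv(small_register(150, "after", seed = 4))
  x <- rep(c(0, 1), length.out = 150)
  f1 <- fit_cox(sv$time, sv$event, x)
  f2 <- fit_cox(3 * sv$time + 7, sv$event, x)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  f3 <- fit_cox(sv$time, sv$event, 1 - x)
  expect_equal(unname(f3$hazard_ratio), 1 / unname(f1$hazard_ratio),
               tolerance = 1e-6)
})

test_that("Cox covariate validation", {
  expect_error(fit_cox(c(1, 2, 3), c(TRUE, TRUE, TRUE), c(1, 1, 1)),
               "non-identifiability")
  expect_error(fit_cox(c(1, 2), c(TRUE, FALSE), c(0, 1)), "fewer than 2")
})

test_that("fits serialize to JSON and back", {
  sv <- register_surv(small_register(120, "before", seed = 8))
  f <- fit_weibull(sv$time, sv$event, period = "before")
  path <- withr::local_tempfile(fileext = ".json")
  write_fits(list(death = f), path)
  back <- read_fits(path)$death
  expect_equal(back$shape, f$shape)
  expect_equal(back$scale, f$scale)
  expect_equal(back$covariance, f$covariance)
})
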