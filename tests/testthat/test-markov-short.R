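# 90-day cohort model: schedule construction, competing risks, trend
# adjustments, propagation.

test_that("competing-risk allocation matches its closed forms", {
  expect_equal(competing_allocation(c(0, 0)), c(0, 0))
  p <- 0.07
  expect_equal(competing_allocation(p), p, tolerance = 1e-12)
  a <- competing_allocation(c(0.1, 0.1))
  expect_equal(sum(a), 1 - 0.9 * 0.9, tolerance = 1e-12)
  expect_equal(a[1], a[2], tolerance = 1e-15)
})

test_that("schedules built from the default conditions are valid", {
  for (period in c("before", "after")) {
    fits <- pathway_from_config(default_generator_config(period))
    sched <- build_schedule(fits, period)
    expect_silent(validate_schedule(sched))
    expect_identical(dim(sched$matrices)[3], 90L)
    # row-stochastic within 1e-9, DEAD absorbing
    rs <- apply(sched$matrices, c(1, 3), sum)
    expect_lt(max(abs(rs - 1)), 1e-9)
  }
})

test_that("a single exit hazard reproduces the marginal daily probability", {
  cfg <- default_generator_config("after")
  fits <- pathway_from_config(cfg)
  sched <- build_schedule(fits, "after")
  i <- match("HASU", sched$states)
  p_exit <- daily_transition_prob(fits$exits$HASU, 0:89)
  p_death <- daily_transition_prob(fits$death, 0:89)
  alloc <- t(vapply(1:90, function(d)
    competing_allocation(c(p_death[d], p_exit[d])), numeric(2)))
  expect_equal(unname(sched$matrices[i, match("DEAD", sched$states), ]),
               alloc[, 1], tolerance = 1e-12)
  row_exit <- apply(sched$matrices[i, , ], 2, sum) -
    sched$matrices[i, i, ] - sched$matrices[i, match("DEAD", sched$states), ]
  expect_equal(unname(row_exit), alloc[, 2], tolerance = 1e-12)
})

test_that("missing fits for reachable wards are reported as configuration errors", {
  fits <- pathway_from_config(default_generator_config("after"))
  fits$exits$SU <- NULL
  expect_error(build_schedule(fits, "after"), "configuration error.*SU")
})

test_that("identity schedules leave the cohort untouched", {
  sched <- toy_schedule(0)
  trace <- run_cohort(sched, 6438)
  expect_true(all(trace$occupancy[, "HOME"] == 6438))
})

test_that("constant-hazard toy cohort follows the geometric closed form", {
  sched <- toy_schedule(0.1)
  trace <- run_cohort(sched, 6438)
  expect_equal(unname(trace$occupancy[91, "HOME"]), 6438 * 0.9^90,
               tolerance = 1e-9)
  sums <- rowSums(trace$occupancy)
  expect_lt(max(abs(sums - 6438)), 1e-6)
  expect_true(all(diff(trace$occupancy[, "DEAD"]) >= -1e-9))
})

test_that("non-stochastic schedules are rejected before propagation", {
  sched <- toy_schedule(0.1)
  sched$matrices[1, 1, 5] <- 0.95    # row now sums to 1.05
  expect_error(run_cohort(sched, 100), "non-stochastic")
  sched2 <- toy_schedule(0.1)
  sched2$matrices[2, 1, 3] <- 0.01   # DEAD leaks
  expect_error(run_cohort(sched2, 100), "DEAD|non-stochastic")
})

test_that("zero mortality adjustment is a bitwise no-op", {
  fits <- pathway_from_config(default_generator_config("before"))
  sched <- build_schedule(fits, "before",
                          adjustment_spec(mortality_enabled = FALSE,
                                          los_enabled = FALSE))
  expect_identical(apply_mortality_adjustment(sched, 0), sched)
})

test_that("mortality adjustment hits the 30-day target exactly (trace oracle)", {
  sched <- toy_schedule(0.01)
  base30 <- (1 - 0.99^30)
  for (method in c("scale", "subtract")) {
    adj <- apply_mortality_adjustment(sched, 2.4, method = method)
    tr <- run_cohort(adj, 100)
    expect_equal(unname(tr$occupancy[31, "DEAD"]), (base30 - 0.024) * 100,
                 tolerance = 1e-7)
    # hazards beyond day 30 untouched; first-month death entries reduced
    expect_equal(adj$matrices[, , 31:90], sched$matrices[, , 31:90])
    expect_true(all(adj$matrices[1, 2, 1:30] < 0.01))
  }
  # on a time-varying hazard the two methods differ day by day
  fits <- pathway_from_config(default_generator_config("before"))
  s0 <- build_schedule(fits, "before", adjustment_spec(mortality_enabled = FALSE,
                                                       los_enabled = FALSE))
  a_sc <- apply_mortality_adjustment(s0, 2.4, method = "scale")
  a_su <- apply_mortality_adjustment(s0, 2.4, method = "subtract")
  expect_gt(max(abs(a_sc$matrices - a_su$matrices)), 1e-6)
})

test_that("infeasible mortality targets are refused", {
  sched <- toy_schedule(0.0005)   # ~1.5% dead at day 30
  expect_error(apply_mortality_adjustment(sched, 2.4), "infeasibility")
})

test_that("LOS adjustment rescales the Weibull mean exactly", {
  fits <- pathway_from_config(default_generator_config("before"))
  sched <- build_schedule(fits, "before",
                          adjustment_spec(mortality_enabled = FALSE,
                                          los_enabled = FALSE))
  expect_identical(apply_los_adjustment(sched, 0), sched)

  # exponential stay: mean 23.1 -> 18.1 rescales the scale directly
  fits$exits$STROKE_REHAB$shape <- 1
  fits$exits$STROKE_REHAB$scale <- 23.1
  s0 <- build_schedule(fits, "before", adjustment_spec(mortality_enabled = FALSE,
                                                       los_enabled = FALSE))
  s1 <- apply_los_adjustment(s0, 5, wards = "STROKE_REHAB")
  expect_equal(s1$fits$exits$STROKE_REHAB$scale, 18.1, tolerance = 1e-9)
  p_new <- daily_transition_prob(s1$fits$exits$STROKE_REHAB, 0)
  expect_equal(p_new, 1 - exp(-1 / 18.1), tolerance = 1e-12)

  # shape 2: implied mean drops by exactly the requested days
  fits$exits$STROKE_REHAB$shape <- 2
  fits$exits$STROKE_REHAB$scale <- 20
  s2 <- build_schedule(fits, "before", adjustment_spec(mortality_enabled = FALSE,
                                                       los_enabled = FALSE))
  s3 <- apply_los_adjustment(s2, 5, wards = "STROKE_REHAB")
  m <- 20 * gamma(1.5)
  expect_equal(s3$fits$exits$STROKE_REHAB$scale * gamma(1.5), m - 5,
               tolerance = 1e-9)
  expect_error(apply_los_adjustment(s2, 30, wards = "STROKE_REHAB"),
               "infeasibility")
})

test_that("the cohort model agrees with the generator's Kaplan-Meier survival", {
  # adjustments off: model survival should track the model-free estimate
  for (period in c("before", "after")) {
    reg <- generate_cohort(default_generator_config(period, n_patients = 4000,
                                                    seed = 31))
    sv <- register_surv(reg)
    km90 <- km_survival_at(km_estimate(sv$time, sv$event), 90)
    fits <- fit_pathway(reg)
    sched <- build_schedule(fits, period,
                            adjustment_spec(mortality_enabled = FALSE,
                                            los_enabled = FALSE))
    trace <- run_cohort(sched, 1)
    s90_model <- 1 - trace$occupancy[91, "DEAD"]
    expect_lt(abs(s90_model - km90), 0.015)
  }
})

test_that("the reconfigured pathway empties its acute units by day 90", {
  fits <- pathway_from_config(default_generator_config("after"))
  trace <- run_cohort(build_schedule(fits, "after"), 6438)
  frac <- sum(trace$occupancy[91, c("HASU", "SU")]) / 6438
  expect_lt(frac, 0.01)
})
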