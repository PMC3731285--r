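# Utilities, cost/QALY accrual, incremental comparison and dominance.

test_that("the default Barthel-utility map passes through both observed anchors", {
  expect_equal(barthel_to_utility(9.3), 0.23, tolerance = 1e-12)
  expect_equal(barthel_to_utility(10.7), 0.30, tolerance = 1e-12)
  expect_true(all(diff(barthel_to_utility(0:20)) >= 0))
  expect_error(barthel_to_utility(21), "out of")
  expect_error(barthel_to_utility(-1), "out of")
})

test_that("utility maps are validated", {
  expect_error(utility_map("lookup", table = rep(0.5, 10)), "21 entries")
  tab <- seq(0, 1, length.out = 21); tab[7] <- 0   # non-monotone permutation
  expect_error(utility_map("lookup", table = tab), "monotone")
  tab2 <- seq(0.5, 1.5, length.out = 21)
  expect_error(utility_map("lookup", table = tab2), "exceed 1")
  lk <- utility_map("lookup", table = seq(-0.2, 0.9, length.out = 21))
  expect_equal(barthel_to_utility(20, lk), 0.9)
})

test_that("accrual arithmetic on toy traces is exact", {
  # 100 persons for 10 days at 50/day
  tr <- toy_schedule(0, n_days = 10)
  trace <- run_cohort(tr, 100)
  costs <- default_cost_schedule()
  costs$daily["HOME"] <- 50
  u <- c(HOME = 0.8, DEAD = 0)
  res <- accrue(trace, costs, u)
  expect_equal(res$total_cost, 100 * 10 * 50)
  expect_equal(res$total_qalys, 100 * 0.8 * 10 / 365.25, tolerance = 1e-12)
  expect_equal(res$deaths, 0)

  # all-dead occupancy accrues nothing
  dead_trace <- trace
  dead_trace$occupancy[, "HOME"] <- 0
  dead_trace$occupancy[, "DEAD"] <- 100
  res0 <- accrue(dead_trace, costs, u)
  expect_equal(res0$total_cost, 0)
  expect_equal(res0$total_qalys, 0)
})

test_that("missing state costs or utilities are configuration errors", {
  trace <- run_cohort(toy_schedule(0.01, states = c("HOME", "DEAD")), 10)
  costs <- default_cost_schedule()
  u <- c(HOME = 0.8, DEAD = 0)
  bad_costs <- costs; bad_costs$daily <- costs$daily[names(costs$daily) != "HOME"]
  expect_error(accrue(trace, bad_costs, u), "configuration error.*HOME")
  expect_error(accrue(trace, costs, c(DEAD = 0)), "configuration error.*HOME")
})

test_that("cost accrual is linear in unit costs and additive over disjoint traces", {
  fits <- pathway_from_config(default_generator_config("after"))
  trace <- run_cohort(build_schedule(fits, "after"), 1000)
  costs <- default_cost_schedule()
  u <- default_short_utilities("after")
  base <- accrue(trace, costs, u, period = "after", oneoff = TRUE)

  doubled <- costs
  doubled$daily <- costs$daily * 2
  doubled$oneoff$unit_cost <- costs$oneoff$unit_cost * 2
  twice <- accrue(trace, doubled, u, period = "after", oneoff = TRUE)
  expect_equal(twice$total_cost, 2 * base$total_cost, tolerance = 1e-12)

  # additivity: a trace split into two halves accrues the same total
  half <- trace; half$occupancy <- trace$occupancy / 2
  half$cohort_size <- trace$cohort_size / 2
  a <- accrue(half, costs, u, period = "after", oneoff = TRUE)
  expect_equal(arm_sum(a, a)$total_cost, base$total_cost, tolerance = 1e-9)
  expect_equal(arm_sum(a, a)$total_qalys, base$total_qalys, tolerance = 1e-9)
})

test_that("the NHS-only perspective never costs more than NHS+PSS", {
  for (period in c("before", "after")) {
    fits <- pathway_from_config(default_generator_config(period))
    trace <- run_cohort(build_schedule(fits, period), 6438)
    u <- default_short_utilities(period)
    full <- accrue(trace, default_cost_schedule("NHS+PSS"), u,
                   period = period, oneoff = TRUE)
    nhs <- accrue(trace, default_cost_schedule("NHS-only"), u,
                  period = period, oneoff = TRUE)
    expect_lte(nhs$total_cost, full$total_cost)
  }
})

test_that("identical arms compare to zero increments with undefined ICERs", {
  fits <- pathway_from_config(default_generator_config("after"))
  trace <- run_cohort(build_schedule(fits, "after"), 6438)
  arm <- accrue(trace, default_cost_schedule(),
                default_short_utilities("after"), period = "after",
                oneoff = TRUE)
  res <- compare_arms(arm, arm)
  expect_equal(res$d_cost, 0)
  expect_equal(res$d_qalys, 0)
  expect_true(is.na(res$icer_per_death_averted))
  expect_true(is.na(res$icer_per_qaly))
})

test_that("dominance labels follow the footnote rule on all four quadrants", {
  expect_equal(cea_report(-5e6, -125, 94)$dominance, "dominant")
  expect_equal(cea_report(+5e6, +125, -94)$dominance, "dominated")
  tro <- cea_report(+1898440, -113, +33)
  expect_equal(tro$dominance, "trade-off")
  expect_equal(tro$icer_per_qaly, 1898440 / 33, tolerance = 1e-12)
  expect_equal(tro$icer_per_death_averted, 1898440 / 113, tolerance = 1e-12)
  sw <- cea_report(-1e6, +10, -20)
  expect_equal(sw$dominance, "trade-off")
  expect_equal(sw$icer_per_qaly, -1e6 / -20, tolerance = 1e-12)
  # cheaper with fewer QALYs but fewer deaths is still dominant by the rule
  expect_equal(cea_report(-1e6, -10, -5)$dominance, "dominant")
})

test_that("mismatched arms are refused", {
  tr1 <- run_cohort(toy_schedule(0.01, n_days = 90), 100)
  tr2 <- run_cohort(toy_schedule(0.01, n_days = 60), 100)
  costs <- default_cost_schedule(); u <- c(HOME = 0.8, DEAD = 0)
  a1 <- accrue(tr1, costs, u); a2 <- accrue(tr2, costs, u)
  expect_error(compare_arms(a1, a2), "horizon")
})
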