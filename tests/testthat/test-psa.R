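# Probabilistic sensitivity analysis and the deterministic scenario battery.

make_fitted_bundle <- function(n_before = 600, n_after = 1200, seed = 17, ...) {
  rb <- generate_cohort(default_generator_config("before", n_patients = n_before,
                                                 seed = seed))
  ra <- generate_cohort(default_generator_config("after", n_patients = n_after,
                                                 seed = seed + 1))
  model_bundle(fits = list(before = fit_pathway(rb), after = fit_pathway(ra)),
               ...)
}

test_that("a fully frozen PSA collapses onto the deterministic point estimate", {
  bundle <- default_model_bundle()
  spec <- psa_spec(n_draws = 4, seed = 3,
                   frozen = c("survival", "mixtures", "event_probs", "costs",
                              "long_transitions"))
  res <- run_psa(bundle, spec)
  expect_equal(nrow(res$draws), 4)
  expect_equal(unname(res$ci[1, ]), unname(res$ci[2, ]))
  expect_equal(unname(res$means[["d_cost_90d"]]),
               res$point$result_90d$d_cost, tolerance = 1e-9)
  expect_equal(unname(res$means[["d_qalys_10y"]]),
               res$point$result_10y$d_qalys, tolerance = 1e-9)
})

test_that("parameter draws are reproducible and match descriptor moments", {
  bundle <- default_model_bundle()
  spec <- psa_spec(n_draws = 3, seed = 11)
  d1 <- draw_parameters(spec, bundle)
  d2 <- draw_parameters(spec, bundle)
  expect_identical(d1, d2)
  expect_false(identical(d1[[1]]$costs$daily, d1[[2]]$costs$daily))

  # event-probability betas: empirical mean near the point probability
  spec2 <- psa_spec(n_draws = 2, seed = 5, ess = c(before = 10, after = 10),
                    frozen = c("survival", "mixtures", "costs",
                               "long_transitions"))
  bundle2 <- bundle
  bundle2$costs$oneoff <- data.frame(item = "x", unit_cost = 100,
                                     prob_before = 0.8, prob_after = 0.8)
  set.seed(5)
  draws <- replicate(4000,
    perturb_bundle(bundle2, spec2)$costs$oneoff$prob_before)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.8), 3 * se + 0.02)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("percentile intervals match the analytic distribution on a linear toy", {
  # only the HASU per-day cost varies (gamma), every other unit cost is 0,
  # so the 90-day cost difference is a known linear function of one gamma
  bundle <- default_model_bundle(
    adjustments = adjustment_spec(mortality_enabled = FALSE,
                                  los_enabled = FALSE))
  bundle$costs$daily[] <- 0
  bundle$costs$daily["HASU"] <- 650
  bundle$costs$cycle[] <- 0
  bundle$costs$oneoff$unit_cost <- 0
  spec <- psa_spec(n_draws = 1200, seed = 9, cost_se_frac = 0.2,
                   frozen = c("survival", "mixtures", "event_probs",
                              "long_transitions"))
  res <- run_psa(bundle, spec)

  trace <- run_cohort(build_schedule(bundle$fits$after, "after",
                                     bundle$adjustments), 6438)
  hasu_person_days <- sum(trace$occupancy[1:90, "HASU"])
  shp <- 1 / 0.2^2
  expected_ci <- hasu_person_days * qgamma(c(0.025, 0.975), shape = shp,
                                           rate = shp / 650)
  got_ci <- res$ci[, "d_cost_90d"]
  expect_lt(abs(got_ci[[1]] - expected_ci[1]) / expected_ci[1], 0.03)
  expect_lt(abs(got_ci[[2]] - expected_ci[2]) / expected_ci[2], 0.03)
  expect_equal(sd(res$draws$d_qalys_90d), 0, tolerance = 1e-9)
})

test_that("PSA means are stable in the number of draws", {
  bundle <- default_model_bundle()
  r1 <- run_psa(bundle, psa_spec(n_draws = 150, seed = 2))
  r2 <- run_psa(bundle, psa_spec(n_draws = 300, seed = 2))
  mc_se <- sd(r2$draws$d_cost_90d) * sqrt(1 / 150 + 1 / 300)
  expect_lt(abs(r1$means[["d_cost_90d"]] - r2$means[["d_cost_90d"]]),
            4 * mc_se)
})

test_that("under the default calibration the reconfiguration is cost-saving and QALY-gaining", {
  bundle <- make_fitted_bundle(800, 1600, seed = 23)
  res <- run_psa(bundle, psa_spec(n_draws = 200, seed = 4))
  expect_lt(res$means[["d_cost_90d"]], 0)
  expect_gt(res$means[["d_qalys_90d"]], 0)
  expect_lt(res$means[["d_cost_10y"]], 0)
  expect_gt(res$means[["d_qalys_10y"]], 0)
})

test_that("CEAC definitions and bounds hold", {
  res <- structure(list(draws = data.frame(
    d_cost_90d = c(-100, -50, 200, 400),
    d_qalys_90d = c(0.01, -0.001, 0.009, 0.008),
    d_cost_10y = 0, d_qalys_10y = 0)), class = "psa_result")
  cc <- ceac(res, thresholds = c(0, 20000, 30000, 50000))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_equal(cc$probability[cc$threshold == 0],
               mean(res$draws$d_cost_90d < 0))
  # hand enumeration at 20,000/QALY: NMB = 20000 dQ - dC
  # hand enumeration: NMB = (300, 30, -20, -240) so 2 of 4 draws qualify
  nmb <- 20000 * res$draws$d_qalys_90d - res$draws$d_cost_90d
  expect_equal(cc$probability[cc$threshold == 20000], mean(nmb > 0))
  expect_equal(cc$probability[cc$threshold == 20000], 0.5)
  expect_error(ceac(res, thresholds = numeric(0)), "empty")

  all_good <- structure(list(draws = data.frame(
    d_cost_90d = c(-10, -20, -5), d_qalys_90d = c(0.1, 0.2, 0.3),
    d_cost_10y = 0, d_qalys_10y = 0)), class = "psa_result")
  expect_true(all(ceac(all_good)$probability == 1))
  # with every draw QALY-gaining the curve is non-decreasing
  pos <- structure(list(draws = data.frame(
    d_cost_90d = rnorm(50, 100, 300), d_qalys_90d = runif(50, 0.01, 0.1),
    d_cost_10y = 0, d_qalys_10y = 0)), class = "psa_result")
  expect_true(all(diff(ceac(pos)$probability) >= 0))
})

test_that("the default threshold grid covers the NICE decision range", {
  res <- structure(list(draws = data.frame(
    d_cost_90d = c(-1, 1), d_qalys_90d = c(0.1, 0.1),
    d_cost_10y = 0, d_qalys_10y = 0)), class = "psa_result")
  cc <- ceac(res)
  expect_true(all(c(0, 20000, 30000, 50000) %in% cc$threshold))
})

test_that("scenario battery produces the reporting table", {
  bundle <- default_model_bundle()
  tab <- run_scenarios(bundle, c("central", "hasu_cost_up_25", "nhs_only"))
  expect_equal(nrow(tab), 6)   # three scenarios at two horizons
  expect_true(all(c("d_cost", "d_deaths", "icer_per_death_averted",
                    "d_qalys", "icer_per_qaly", "dominance") %in% names(tab)))

  central <- run_model(bundle)
  c90 <- tab[tab$scenario == "central" & tab$horizon == "90d", ]
  expect_equal(c90$d_cost, central$result_90d$d_cost)

  # HASU cost +25% changes only cost columns, not outcomes
  h90 <- tab[tab$scenario == "hasu_cost_up_25" & tab$horizon == "90d", ]
  expect_equal(h90$d_deaths, c90$d_deaths)
  expect_equal(h90$d_qalys, c90$d_qalys)
  expect_gt(h90$d_cost, c90$d_cost)   # the after arm uses the HASU

  # NHS-only perspective cannot raise either arm's cost
  full <- run_model(bundle)
  nhs_b <- run_model(default_scenarios()$nhs_only$modify(bundle))
  expect_lte(nhs_b$before$arm_90d$total_cost, full$before$arm_90d$total_cost)
  expect_lte(nhs_b$after$arm_90d$total_cost, full$after$arm_90d$total_cost)

  expect_error(run_scenarios(bundle, "not_a_scenario"),
               "unknown scenario.*available")
})

test_that("the no-op scenario reproduces the central deterministic estimate", {
  bundle <- default_model_bundle()
  tab <- run_scenarios(bundle, c("central"))
  res <- run_model(bundle)
  expect_equal(tab$d_cost[tab$horizon == "90d"], res$result_90d$d_cost)
  expect_equal(tab$d_qalys[tab$horizon == "10y"], res$result_10y$d_qalys)
})
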