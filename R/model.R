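#' Assemble the full decision-model bundle
#'
#' Collects everything the deterministic pipeline needs: per-period pathway
#' fits, trend adjustments (applied to the "before" arm only), cost
#' schedule, utilities, long-run transition matrices and Barthel mixtures,
#' discounting and cohort size. The bundle is the unit the scenario runner
#' and the probabilistic sensitivity analysis perturb.
#'
#' @param fits Named list `list(before = , after = )` of `pathway_fits`.
#' @param adjustments An [adjustment_spec()].
#' @param costs A [cost_schedule()].
#' @param umap A [utility_map()].
#' @param short_utilities Named list of per-period state-utility vectors.
#' @param long_transitions Named list of per-period 5 x 5 matrices (or one
#'   matrix used for both).
#' @param long_utilities Utility vector over `LONG_STATES`.
#' @param barthel_mix Named list of per-period length-3 home-band mixtures.
#' @param inpatient_rule Allocation of patients still in hospital at 90
#'   days, see [seed_from_short_run()].
#' @param discount A [discount_spec()] (10-year horizon only).
#' @param cohort_size Modelled population per arm (default 6438, the annual
#'   number of strokes in the modelled city).
#' @param mimic_fraction Fraction of the "after" cohort that are stroke
#'   mimics following a benign one-day pathway (scenario lever; default 0).
#' @return A `model_bundle` list.
#' @export
model_bundle <- function(fits, adjustments = adjustment_spec(),
                         costs = default_cost_schedule(),
                         umap = utility_map(),
                         short_utilities = list(
                           before = default_short_utilities("before", umap),
                           after = default_short_utilities("after", umap)),
                         long_transitions = default_long_transitions(),
                         long_utilities = default_long_utilities(umap),
                         barthel_mix = list(before = c(0.45, 0.22, 0.33),
                                            after = c(0.55, 0.22, 0.23)),
                         inpatient_rule = "institutional",
                         discount = discount_spec(),
                         cohort_size = 6438,
                         mimic_fraction = 0) {
  if (is.matrix(long_transitions))
    long_transitions <- list(before = long_transitions,
                             after = long_transitions)
  structure(list(fits = fits, adjustments = adjustments, costs = costs,
                 umap = umap, short_utilities = short_utilities,
                 long_transitions = long_transitions,
                 long_utilities = long_utilities, barthel_mix = barthel_mix,
                 inpatient_rule = inpatient_rule, discount = discount,
                 cohort_size = cohort_size, mimic_fraction = mimic_fraction),
            class = "model_bundle")
}

#' Default model bundle from the generating study conditions
#'
#' Builds the bundle directly from the package's default generator
#' configurations ([default_generator_config()]) rather than from fitted
#' registers: useful as a deterministic reference model.
#'
#' @param ... Overrides passed to [model_bundle()].
#' @return A `model_bundle`.
#' @export
default_model_bundle <- function(...) {
  model_bundle(fits = list(
    before = pathway_from_config(default_generator_config("before")),
    after = pathway_from_config(default_generator_config("after"))), ...)
}

# benign stroke-mimic pathway: one day on the admission ward, home after,
# no excess mortality; used to dilute the "after" arm in the mimic scenario
.mimic_arm <- function(bundle, horizon_days, n) {
  costs <- bundle$costs
  first_ward <- names(bundle$fits$after$init)[1]
  daily <- costs$daily
  if (costs$perspective == "NHS-only")
    daily[intersect(costs$pss_states, names(daily))] <- 0
  oneoff <- costs$oneoff
  pp_cost <- daily[[first_ward]] +
    sum(oneoff$unit_cost[oneoff$item %in% c("ambulance", "head_ct")])
  u_home <- bundle$long_utilities[["HOME_INDEPENDENT"]]
  if (horizon_days <= 90) {
    qaly_pp <- u_home * horizon_days / 365.25
    cost_pp <- pp_cost + daily[["HOME"]] * (horizon_days - 1)
  } else {
    init <- stats::setNames(c(n, 0, 0, 0, 0), LONG_STATES)
    lt <- run_long_cohort(init, bundle$long_transitions$after, 40L)
    la <- accrue(lt, costs, bundle$long_utilities,
                 discount = bundle$discount, day_offset = 90)
    qaly_pp <- u_home * 90 / 365.25 + la$total_qalys / n
    cost_pp <- pp_cost + daily[["HOME"]] * 89 + la$total_cost / n
  }
  structure(list(total_cost = n * cost_pp, total_qalys = n * qaly_pp,
                 deaths = 0, per_patient_cost = cost_pp, cohort_size = n,
                 horizon_days = horizon_days,
                 components = c(residence = NA_real_, oneoff = NA_real_)),
            class = "arm_result")
}

#' Run one arm of the decision model
#'
#' Builds the daily schedule (trend adjustments applied in the "before"
#' period), propagates the 6,438-patient cohort to 90 days, accrues the
#' 90-day costs and QALYs (undiscounted, with one-off admission costs),
#' then seeds the long-run model from the day-90 occupancy and accrues the
#' discounted 10-year totals (the short-run contribution to the 10-year
#' horizon is discounted at mid-cycle days from admission).
#'
#' @param bundle A `model_bundle`.
#' @param period `"before"` or `"after"`.
#' @return List with `trace_short`, `trace_long`, `arm_90d`, `arm_10y`.
#' @export
run_arm <- function(bundle, period) {
  period <- match.arg(period, c("before", "after"))
  fits <- bundle$fits[[period]]
  sched <- build_schedule(fits, period, bundle$adjustments)
  n <- bundle$cohort_size
  mim <- if (period == "after") bundle$mimic_fraction else 0
  n_model <- n * (1 - mim)

  trace <- run_cohort(sched, n_model)
  u <- bundle$short_utilities[[period]]
  arm90 <- accrue(trace, bundle$costs, u, period = period, oneoff = TRUE)
  arm90_disc <- accrue(trace, bundle$costs, u, period = period,
                       oneoff = TRUE, discount = bundle$discount)

  init_long <- seed_from_short_run(trace, bundle$barthel_mix[[period]],
                                   bundle$inpatient_rule)
  trace_long <- run_long_cohort(init_long, bundle$long_transitions[[period]], 40L)
  arm_long <- accrue(trace_long, bundle$costs, bundle$long_utilities,
                     discount = bundle$discount, day_offset = 90)
  arm10 <- structure(list(
    total_cost = arm90_disc$total_cost + arm_long$total_cost,
    total_qalys = arm90_disc$total_qalys + arm_long$total_qalys,
    deaths = arm90$deaths +
      (trace_long$occupancy[41, "DEAD"] - trace_long$occupancy[1, "DEAD"]),
    per_patient_cost = NA_real_, cohort_size = n_model,
    horizon_days = 3690,
    components = c(short = arm90_disc$total_cost, long = arm_long$total_cost)),
    class = "arm_result")
  arm10$per_patient_cost <- arm10$total_cost / n_model

  if (mim > 0) {
    m90 <- .mimic_arm(bundle, 90, n * mim)
    m10 <- .mimic_arm(bundle, 3690, n * mim)
    arm90 <- arm_sum(arm90, m90)
    arm10 <- arm_sum(arm10, m10)
  }
  list(trace_short = trace, trace_long = trace_long,
       arm_90d = arm90, arm_10y = arm10)
}

#' Run the full before/after comparison
#'
#' @param bundle A `model_bundle`.
#' @return List with per-arm runs (`before`, `after`) and incremental
#'   results `result_90d` and `result_10y` (after minus before).
#' @export
run_model <- function(bundle) {
  b <- run_arm(bundle, "before")
  a <- run_arm(bundle, "after")
  list(before = b, after = a,
       result_90d = compare_arms(b$arm_90d, a$arm_90d),
       result_10y = compare_arms(b$arm_10y, a$arm_10y))
}
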