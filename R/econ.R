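#' Barthel-to-utility mapping
#'
#' Health-state utilities are derived from the Barthel activities-of-daily-
#' living index. The default is an affine map `u = 0.05 * BI - 0.235`,
#' clipped to \[-0.235, 1\]: a calibration stand-in chosen to pass through
#' the two observed (mean Barthel, mean utility) anchor pairs (9.3, 0.23)
#' and (10.7, 0.30), not a published mapping algorithm. A lookup table over
#' the 21 Barthel levels may be supplied instead; it must be monotone
#' non-decreasing with utilities at most 1.
#'
#' @param type `"affine"` or `"lookup"`.
#' @param slope,intercept Affine parameters.
#' @param clip Length-2 clip bounds for the affine map.
#' @param table Length-21 utility vector for scores 0..20 (lookup type).
#' @return A `utility_map` list.
#' @export
utility_map <- function(type = c("affine", "lookup"), slope = 0.05,
                        intercept = -0.235, clip = c(-0.235, 1),
                        table = NULL) {
  type <- match.arg(type)
  if (type == "lookup") {
    if (is.null(table) || length(table) != 21)
      stop("validation error: lookup table must have 21 entries (scores 0..20)")
    if (any(diff(table) < 0))
      stop("validation error: utility must be monotone non-decreasing in Barthel")
    if (any(table > 1)) stop("validation error: utility cannot exceed 1")
  } else {
    if (slope < 0) stop("validation error: affine slope must be >= 0")
    if (clip[2] > 1) stop("validation error: utility cannot exceed 1")
  }
  structure(list(type = type, slope = slope, intercept = intercept,
                 clip = clip, table = table), class = "utility_map")
}

#' Convert Barthel scores to utilities
#'
#' @param score Barthel scores in \[0, 20\].
#' @param map A [utility_map()].
#' @return Utility values (monotone in the score, at most 1).
#' @export
barthel_to_utility <- function(score, map = utility_map()) {
  stopifnot(inherits(map, "utility_map"))
  if (any(score < 0 | score > 20)) stop("Barthel score out of [0, 20]")
  if (map$type == "lookup") return(map$table[round(score) + 1])
  pmin(pmax(map$slope * score + map$intercept, map$clip[1]), map$clip[2])
}

#' Cost schedule for both models
#'
#' Unit costs in 2010/11 UK pounds. Per-day costs apply to the short-run
#' ward/discharge states, per-cycle (90-day) costs to the long-run states.
#' One-off event costs (ambulance conveyance, imaging, interventions,
#' thrombolysis drug and delivery) are applied as expected values at
#' admission: probability x unit cost x cohort. All default values are
#' documented assumptions standing in for unpublished unit-cost tables.
#' Under the `"NHS-only"` perspective the per-day/per-cycle costs of the
#' personal-social-services states in `pss_states` are excluded.
#'
#' @param daily Named per-day costs over `SHORT_STATES`.
#' @param cycle Named per-90-day-cycle costs over `LONG_STATES`.
#' @param oneoff `data.frame` with columns `item`, `unit_cost`,
#'   `prob_before`, `prob_after`.
#' @param perspective `"NHS+PSS"` or `"NHS-only"`.
#' @param pss_states States whose residence costs are social care.
#' @return A `cost_schedule` list.
#' @export
cost_schedule <- function(daily, cycle, oneoff,
                          perspective = c("NHS+PSS", "NHS-only"),
                          pss_states = c("HOME", "NURSING_HOME",
                                         "INSTITUTIONAL_CARE")) {
  perspective <- match.arg(perspective)
  if (any(daily < 0) || any(cycle < 0) || any(oneoff$unit_cost < 0))
    stop("validation error: costs must be >= 0")
  .assert_prob(oneoff$prob_before, "oneoff$prob_before")
  .assert_prob(oneoff$prob_after, "oneoff$prob_after")
  structure(list(daily = daily, cycle = cycle, oneoff = oneoff,
                 perspective = perspective, pss_states = pss_states),
            class = "cost_schedule")
}

#' Default cost schedule (assumption values)
#'
#' @param perspective `"NHS+PSS"` or `"NHS-only"`.
#' @return A [cost_schedule()] populated with the package's documented
#'   stand-in unit costs (2010/11 UK pounds) and the observed per-period
#'   imaging/intervention and thrombolysis rates.
#' @export
default_cost_schedule <- function(perspective = "NHS+PSS") {
  cost_schedule(
    daily = c(HASU = 650, ASU = 350, SU = 350, STROKE_REHAB = 250,
              MEDICAL = 250, SURGICAL = 350, ICU = 1400,
              HOME = 15, HOME_ESD = 60, NURSING_HOME = 110, DEAD = 0),
    cycle = c(HOME_INDEPENDENT = 300, HOME_MODERATE = 900,
              HOME_DEPENDENT = 2500, INSTITUTIONAL_CARE = 9000, DEAD = 0),
    oneoff = data.frame(
      item = c("ambulance", "head_ct", "head_mri", "ct_angiography",
               "echocardiogram", "carotid_stenting", "neurosurgery",
               "thrombolysis"),
      unit_cost = c(250, 100, 260, 160, 100, 4000, 8000, 650),
      prob_before = c(1.00, 0.95, 0.51, 0.40, 0.28, 0.11, 0.06, 0.05),
      prob_after  = c(1.00, 0.94, 0.68, 0.63, 0.49, 0.14, 0.01, 0.13)),
    perspective = perspective)
}

#' Default state utilities for the short-run model
#'
#' Each ward/discharge state carries the utility of its typical occupant
#' under the Barthel-to-utility map: inpatients at the period's mean
#' admission Barthel, home states at the improved 90-day level, nursing
#' home at a low dependency level. Documented assumption values.
#'
#' @param period `"before"` or `"after"`.
#' @param map A [utility_map()].
#' @return Named utility vector over the period's states.
#' @export
default_short_utilities <- function(period, map = utility_map()) {
  period <- match.arg(period, c("before", "after"))
  bi <- if (period == "before")
    c(inpatient = 9.3, home = 12.3, nh = 5) else
    c(inpatient = 10.7, home = 14.7, nh = 5)
  u <- stats::setNames(numeric(length(period_states(period))),
                       period_states(period))
  u[intersect(.INPATIENT_STATES, names(u))] <-
    barthel_to_utility(bi["inpatient"], map)
  u[c("HOME", "HOME_ESD")] <- barthel_to_utility(bi["home"], map)
  u["NURSING_HOME"] <- barthel_to_utility(bi["nh"], map)
  u["DEAD"] <- 0
  u
}

#' Default state utilities for the long-run model
#'
#' Home bands take the utility of their Barthel mid-point; institutional
#' care a low dependency level. Documented assumption values.
#'
#' @param map A [utility_map()].
#' @return Named utility vector over `LONG_STATES`.
#' @export
default_long_utilities <- function(map = utility_map()) {
  c(HOME_INDEPENDENT = barthel_to_utility(17.5, map),
    HOME_MODERATE = barthel_to_utility(12, map),
    HOME_DEPENDENT = barthel_to_utility(4.5, map),
    INSTITUTIONAL_CARE = barthel_to_utility(6, map),
    DEAD = 0)
}

#' Accrue costs and QALYs over a cohort trace
#'
#' Residence costs: sum over cycles and states of occupancy x unit cost x
#' discount factor (per-day costs for daily traces, per-cycle costs for
#' 90-day traces; the `"NHS-only"` perspective zeroes social-care states).
#' QALYs: occupancy x state utility x cycle length / 365.25 x discount.
#' Occupancy at the start of each cycle is used; with daily cycles a
#' half-cycle correction would change results by well under one part in a
#' thousand and is omitted. One-off event costs, when enabled, add
#' probability x unit cost x cohort at admission. Discounting, when a spec
#' is given, is applied at the mid-cycle day offset by `day_offset` (the
#' long-run model starts at day 90).
#'
#' @param trace A `cohort_trace` (short- or long-run).
#' @param costs A [cost_schedule()].
#' @param utilities Named utility vector covering every state in the trace.
#' @param period `"before"` or `"after"`; needed when `oneoff = TRUE`.
#' @param discount Optional [discount_spec()].
#' @param oneoff Apply one-off admission event costs?
#' @param day_offset Days between time origin and the trace's cycle 0.
#' @return An `arm_result` list: `total_cost`, `total_qalys`, `deaths`,
#'   `per_patient_cost`, `cohort_size`, `horizon_days`, `components`.
#' @export
accrue <- function(trace, costs, utilities, period = NULL, discount = NULL,
                   oneoff = FALSE, day_offset = 0) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(costs, "cost_schedule"))
  states <- trace$states
  unit <- if (trace$cycle_days == 1) costs$daily else costs$cycle
  missing_c <- setdiff(states, names(unit))
  if (length(missing_c))
    stop("configuration error: no unit cost for state(s): ",
         paste(missing_c, collapse = ", "))
  missing_u <- setdiff(states, names(utilities))
  if (length(missing_u))
    stop("configuration error: no utility for state(s): ",
         paste(missing_u, collapse = ", "))
  unit <- unit[states]
  if (costs$perspective == "NHS-only")
    unit[intersect(costs$pss_states, states)] <- 0
  u <- utilities[states]
  if (any(u > 1)) stop("validation error: utility cannot exceed 1")

  n_cycles <- nrow(trace$occupancy) - 1L
  occ <- trace$occupancy[seq_len(n_cycles), , drop = FALSE]
  mid_day <- day_offset + (seq_len(n_cycles) - 0.5) * trace$cycle_days
  disc <- if (is.null(discount)) rep(1, n_cycles) else
    discount_factor(discount, mid_day)

  residence_cost <- sum((occ %*% unit) * disc)
  qalys <- sum((occ %*% u) * disc) * trace$cycle_days / 365.25

  oneoff_cost <- 0
  if (oneoff) {
    if (is.null(period))
      stop("configuration error: 'period' required for one-off event costs")
    period <- match.arg(period, c("before", "after"))
    p <- costs$oneoff[[paste0("prob_", period)]]
    oneoff_cost <- sum(p * costs$oneoff$unit_cost) * trace$cohort_size
  }
  idead <- match("DEAD", states)
  deaths <- unname(trace$occupancy[n_cycles + 1L, idead] -
                   trace$occupancy[1L, idead])
  total <- residence_cost + oneoff_cost
  structure(list(total_cost = total, total_qalys = qalys, deaths = deaths,
                 per_patient_cost = total / trace$cohort_size,
                 cohort_size = trace$cohort_size,
                 horizon_days = n_cycles * trace$cycle_days + day_offset,
                 components = c(residence = residence_cost,
                                oneoff = oneoff_cost)),
            class = "arm_result")
}

#' Combine the results of two disjoint traces
#'
#' @param a,b `arm_result` objects with equal horizons.
#' @return Their sum as an `arm_result` (cohorts pooled).
#' @export
arm_sum <- function(a, b) {
  stopifnot(a$horizon_days == b$horizon_days)
  structure(list(total_cost = a$total_cost + b$total_cost,
                 total_qalys = a$total_qalys + b$total_qalys,
                 deaths = a$deaths + b$deaths,
                 per_patient_cost = (a$total_cost + b$total_cost) /
                   (a$cohort_size + b$cohort_size),
                 cohort_size = a$cohort_size + b$cohort_size,
                 horizon_days = a$horizon_days,
                 components = a$components + b$components),
            class = "arm_result")
}

#' Incremental cost-effectiveness report from raw increments
#'
#' The reporting rule: "dominant" means the new arm costs less and has
#' either fewer deaths or more QALYs; "dominated" is the mirror image;
#' otherwise the trade-off ICERs are reported - incremental cost per death
#' averted (when deaths fall) and incremental cost per QALY gained.
#'
#' @param d_cost Incremental total cost (after - before).
#' @param d_deaths Incremental deaths (after - before; negative = averted).
#' @param d_qalys Incremental QALYs (after - before).
#' @return An `econ_result` list with `icer_per_death_averted` and
#'   `icer_per_qaly` (`NA` where dominance makes them undefined) and a
#'   `dominance` label in `{"dominant", "dominated", "trade-off"}`.
#' @export
cea_report <- function(d_cost, d_deaths, d_qalys) {
  dominance <- if (d_cost < 0 && (d_deaths < 0 || d_qalys > 0)) "dominant"
  else if (d_cost > 0 && (d_deaths > 0 || d_qalys < 0) &&
           !(d_deaths < 0 && d_qalys > 0)) "dominated"
  else "trade-off"
  icer_death <- if (dominance == "trade-off" && d_deaths < 0)
    d_cost / (-d_deaths) else NA_real_
  icer_qaly <- if (dominance == "trade-off" && d_qalys != 0)
    d_cost / d_qalys else NA_real_
  # a cost increase bought only at a QALY gain is an ordinary trade-off
  if (d_cost > 0 && d_qalys > 0) {
    dominance <- "trade-off"
    icer_qaly <- d_cost / d_qalys
    icer_death <- if (d_deaths < 0) d_cost / (-d_deaths) else NA_real_
  }
  structure(list(d_cost = d_cost, d_deaths = d_deaths, d_qalys = d_qalys,
                 icer_per_death_averted = icer_death,
                 icer_per_qaly = icer_qaly, dominance = dominance),
            class = "econ_result")
}

#' Compare two model arms
#'
#' Increments are computed after minus before; ICERs are reported only in
#' the trade-off quadrants; identical arms yield zero increments with both
#' ICERs undefined.
#'
#' @param before,after `arm_result` objects with equal cohort size and
#'   horizon.
#' @return An `econ_result` (see [cea_report()]) with per-arm totals
#'   attached.
#' @export
compare_arms <- function(before, after) {
  stopifnot(inherits(before, "arm_result"), inherits(after, "arm_result"))
  if (before$horizon_days != after$horizon_days)
    stop("mismatched horizons: ", before$horizon_days, " vs ",
         after$horizon_days)
  if (before$cohort_size != after$cohort_size)
    stop("mismatched cohort sizes")
  d_cost <- after$total_cost - before$total_cost
  d_deaths <- after$deaths - before$deaths
  d_qalys <- after$total_qalys - before$total_qalys
  out <- cea_report(d_cost, d_deaths, d_qalys)
  if (d_cost == 0 && d_deaths == 0 && d_qalys == 0) out$dominance <- "trade-off"
  out$before <- before
  out$after <- after
  out$d_cost_per_patient <- d_cost / before$cohort_size
  out
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("Incremental result (after - before):\n"))
  cat(sprintf("  d_cost   : %12.0f\n", x$d_cost))
  cat(sprintf("  d_deaths : %12.1f\n", x$d_deaths))
  cat(sprintf("  d_QALYs  : %12.1f\n", x$d_qalys))
  cat(sprintf("  ICER/death averted : %s\n",
              if (is.na(x$icer_per_death_averted)) x$dominance
              else sprintf("%.0f", x$icer_per_death_averted)))
  cat(sprintf("  ICER/QALY          : %s\n",
              if (is.na(x$icer_per_qaly)) x$dominance
              else sprintf("%.0f", x$icer_per_qaly)))
  invisible(x)
}
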