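#' National-trend adjustment specification
#'
#' The before/after contrast must not credit the reconfiguration with secular
#' improvements seen nationally over the same years. Two adjustments are
#' applied to the "before" arm: a reduction of cumulative 30-day mortality by
#' `mortality_pp_30d` percentage points (national audit trend: 20.7% to
#' 18.3%, i.e. 2.4 points), and a reduction of the mean stroke-unit length
#' of stay by `su_los_days` days (23.1 to 18.1 nationally).
#'
#' @param mortality_pp_30d Percentage-point drop in cumulative 30-day
#'   mortality (>= 0).
#' @param su_los_days Days removed from the mean stroke-unit stay (>= 0).
#' @param mortality_enabled,los_enabled Switch each adjustment on/off.
#' @param su_wards Wards whose exit-time scale absorbs the LOS reduction;
#'   default `"STROKE_REHAB"`, the ongoing stroke-unit stay of the previous
#'   pathway.
#' @param mortality_method `"scale"` (default): uniformly rescale the
#'   death hazard over days 0-29; `"subtract"`: remove the deaths at the
#'   day-30 boundary only.
#' @return An `adjustment_spec` list.
#' @export
adjustment_spec <- function(mortality_pp_30d = 2.4, su_los_days = 5.0,
                            mortality_enabled = TRUE, los_enabled = TRUE,
                            su_wards = "STROKE_REHAB",
                            mortality_method = c("scale", "subtract")) {
  if (mortality_pp_30d < 0) stop("mortality_pp_30d must be >= 0")
  if (su_los_days < 0) stop("su_los_days must be >= 0")
  structure(list(mortality_pp_30d = mortality_pp_30d,
                 su_los_days = su_los_days,
                 mortality_enabled = mortality_enabled,
                 los_enabled = los_enabled,
                 su_wards = su_wards,
                 mortality_method = match.arg(mortality_method)),
            class = "adjustment_spec")
}

#' Estimate the short-run pathway model from a register
#'
#' Fits, per period, (i) the marginal death-time Weibull that drives the
#' cohort model's daily death probabilities (the cohort model needs the
#' population-average hazard, so no covariates enter this fit; with
#' `age_covariate = TRUE` an additional age-adjusted fit with age centred
#' at the register mean is attached as `death_age` for reporting), (ii) a
#' ward-exit-time Weibull for every ward visited (time measured in days
#' from admission; deaths on the ward and administrative censoring are
#' treated as censoring for the exit time), and (iii) empirical destination
#' mixtures over the next state after each ward exit, plus the
#' first-admission-ward initial distribution.
#'
#' @param register A validated register `data.frame` (one period).
#' @param age_covariate Also fit the age-adjusted death model?
#' @return A `pathway_fits` list: `period`, `death` (a `survival_fit`),
#'   `exits` (named list of `survival_fit`), `destinations` (named list of
#'   mixtures), `dest_counts` (raw counts, used for Dirichlet uncertainty),
#'   `init` (first-ward mixture), `init_counts`.
#' @export
fit_pathway <- function(register, age_covariate = FALSE) {
  period <- unique(register$period)
  if (length(period) != 1)
    stop("register must contain a single period; got: ",
         paste(period, collapse = ", "))
  died <- !is.na(register$death_day)
  times <- ifelse(died, register$death_day, register$censor_day)
  death_fit <- fit_weibull(times, died, period = period)
  death_age <- if (age_covariate)
    fit_weibull(times, died, period = period,
                covariates = data.frame(age = register$age -
                                          mean(register$age))) else NULL

  eps <- register_episodes(register)
  exit_times <- list(); exit_events <- list(); dest <- list()
  first_ward <- character(length(eps))
  for (i in seq_along(eps)) {
    e <- eps[[i]]
    first_ward[i] <- e$ward_state[1]
    for (j in seq_len(nrow(e))) {
      w <- e$ward_state[j]
      if (!w %in% .INPATIENT_STATES) next
      exited_alive <- j < nrow(e)
      exit_times[[w]] <- c(exit_times[[w]], e$exit_day[j])
      exit_events[[w]] <- c(exit_events[[w]], exited_alive)
      if (exited_alive) dest[[w]] <- c(dest[[w]], e$ward_state[j + 1])
    }
  }
  exits <- list(); destinations <- list(); dest_counts <- list()
  for (w in names(exit_times)) {
    exits[[w]] <- tryCatch(
      fit_weibull(exit_times[[w]], exit_events[[w]], period = period),
      error = function(e)
        .sparse_exponential_fit(exit_times[[w]], exit_events[[w]], period))
    tab <- table(dest[[w]])
    if (length(tab) == 0) {
      # ward never observed to discharge anyone: default destination home
      dest_counts[[w]] <- c(HOME = 0.5)
    } else {
      dest_counts[[w]] <- stats::setNames(as.numeric(tab), names(tab))
    }
    destinations[[w]] <- dest_counts[[w]] / sum(dest_counts[[w]])
  }
  init_tab <- table(factor(first_ward, levels = period_states(period)))
  init_tab <- init_tab[init_tab > 0]
  init_counts <- stats::setNames(as.numeric(init_tab), names(init_tab))
  structure(list(period = period, death = death_fit, death_age = death_age,
                 exits = exits,
                 destinations = destinations, dest_counts = dest_counts,
                 init = init_counts / sum(init_counts),
                 init_counts = init_counts),
            class = "pathway_fits")
}

# Exponential stand-in for wards too sparse for a Weibull fit (fewer than
# two observed exits): Jeffreys-style regularized rate so that wards seen
# once or never still carry a finite, weakly informative exit hazard.
.sparse_exponential_fit <- function(times, events, period) {
  times[times <= 0] <- 0.5
  d <- sum(events)
  scale <- (sum(times) + 0.5) / (d + 0.5)
  V <- matrix(c(1 / (d + 0.5), 0, 0, 0), 2, 2,
              dimnames = list(c("log_scale", "log_shape"),
                              c("log_scale", "log_shape")))
  structure(list(family = "exponential", shape = 1, scale = scale,
                 coefficients = NULL, covariance = V, loglik = NA_real_,
                 n = length(times), n_events = d, period = period),
            class = "survival_fit")
}

#' Build pathway "fits" directly from a generator configuration
#'
#' Convenience constructor producing the same `pathway_fits` structure from
#' known generating parameters instead of estimated ones (useful for toy
#' models and oracle checks). Ward exit times are interpreted as measured
#' from admission.
#'
#' @param config A `generator_config`.
#' @param dest_ess Effective sample size attached to destination mixtures
#'   (used only for probabilistic-uncertainty draws).
#' @return A `pathway_fits` object.
#' @export
pathway_from_config <- function(config, dest_ess = 100) {
  stopifnot(inherits(config, "generator_config"))
  mk_fit <- function(shape, scale) {
    structure(list(family = "weibull", shape = shape, scale = scale,
                   coefficients = NULL,
                   covariance = matrix(0, 2, 2,
                     dimnames = list(c("log_scale", "log_shape"),
                                     c("log_scale", "log_shape"))),
                   loglik = NA_real_, n = NA_integer_, n_events = NA_integer_,
                   period = config$period),
              class = "survival_fit")
  }
  exits <- lapply(config$ward_exit, function(w) mk_fit(w$shape, w$scale))
  structure(list(period = config$period,
                 death = mk_fit(config$death_shape, config$death_scale),
                 exits = exits,
                 destinations = config$ward_destinations,
                 dest_counts = lapply(config$ward_destinations,
                                      function(d) d * dest_ess),
                 init = config$first_ward_probs,
                 init_counts = config$first_ward_probs * dest_ess),
            class = "pathway_fits")
}

#' Within-cycle competing-risk allocation
#'
#' Converts marginal per-cycle probabilities of competing events into
#' allocated probabilities: each marginal `p` becomes a rate
#' `-ln(1 - p)`, the total event probability is one minus the survivor of
#' the summed rates, and it is shared in proportion to the rates. The
#' allocation is order-independent and reduces to the marginals when only
#' one risk is present.
#'
#' @param p Vector of marginal per-cycle probabilities (each in \[0, 1)).
#' @return Vector of allocated probabilities, summing to
#'   `1 - prod(1 - p)`.
#' @export
competing_allocation <- function(p) {
  .assert_prob(p, "p")
  if (any(p >= 1)) stop("marginal probabilities must be < 1")
  r <- -log(1 - p)
  tot <- sum(r)
  if (tot == 0) return(rep(0, length(p)))
  (1 - exp(-tot)) * r / tot
}

# states reachable from the initial mixture through destination edges
.reachable_wards <- function(fits) {
  reach <- intersect(names(fits$init), .INPATIENT_STATES)
  repeat {
    nxt <- unique(unlist(lapply(reach, function(w)
      intersect(names(fits$destinations[[w]]), .INPATIENT_STATES))))
    new <- setdiff(nxt, reach)
    if (!length(new)) return(reach)
    reach <- c(reach, new)
  }
}

#' Build the daily transition schedule of the 90-day model
#'
#' Converts fitted per-day marginal probabilities into one row-stochastic
#' matrix per day 0..`n_days`-1. Within a day, death and ward exit compete:
#' each marginal probability `p` is converted to a rate `-ln(1 - p)`,
#' the total leaving probability is `1 - exp(-sum of rates)` and is allocated
#' proportionally to the rates (order-independent). Ward-exit mass is split
#' over the ward's destination mixture. Discharged states carry the death
#' hazard only; `DEAD` is absorbing. For the "before" period the
#' national-trend adjustments of `adjustments` are applied: first the
#' stroke-unit length-of-stay reduction (rescaling the exit-time scale so
#' the implied mean drops by the requested days), then the 30-day mortality
#' reduction (see [apply_mortality_adjustment()]).
#'
#' @param fits A `pathway_fits` object.
#' @param period `"before"` or `"after"` (defaults to the fits' period).
#' @param adjustments An [adjustment_spec()]; adjustments only ever apply to
#'   the "before" period.
#' @param n_days Number of daily cycles (default 90).
#' @return A `transition_schedule`: `states`, `matrices` (S x S x n_days
#'   array), `init` (initial distribution), `fits` (provenance), `period`.
#' @export
build_schedule <- function(fits, period = fits$period,
                           adjustments = adjustment_spec(), n_days = 90L) {
  stopifnot(inherits(fits, "pathway_fits"))
  period <- match.arg(period, c("before", "after"))

  reach <- .reachable_wards(fits)
  missing_fit <- setdiff(reach, names(fits$exits))
  if (length(missing_fit))
    stop("configuration error: no exit fit for reachable ward(s): ",
         paste(missing_fit, collapse = ", "))
  missing_dest <- setdiff(reach, names(fits$destinations))
  if (length(missing_dest))
    stop("configuration error: no destination mixture for reachable ward(s): ",
         paste(missing_dest, collapse = ", "))

  if (period == "before" && adjustments$los_enabled &&
      adjustments$su_los_days > 0)
    fits <- .reduce_los(fits, adjustments$su_los_days, adjustments$su_wards)

  sched <- .assemble_schedule(fits, period, n_days)
  sched$adjustments <- adjustments
  if (period == "before" && adjustments$mortality_enabled &&
      adjustments$mortality_pp_30d > 0)
    sched <- apply_mortality_adjustment(sched, adjustments$mortality_pp_30d,
                                        method = adjustments$mortality_method)
  sched
}

.reduce_los <- function(fits, days, wards) {
  wards <- intersect(wards, names(fits$exits))
  for (w in wards) {
    f <- fits$exits[[w]]
    m <- .weib_mean(f$shape, f$scale)
    if (days >= m)
      stop("infeasibility error: LOS reduction of ", days,
           " days is >= current mean stay (", signif(m, 4), " days) on ", w)
    fits$exits[[w]]$scale <- f$scale * (m - days) / m
  }
  fits
}

# per-day event probability via cumulative-hazard increments: identical to
# 1 - S(d+1)/S(d) but immune to survival underflow at late days
.daily_p <- function(fit, days) {
  dH <- ((days + 1) / fit$scale)^fit$shape - (days / fit$scale)^fit$shape
  1 - exp(-dH)
}

.assemble_schedule <- function(fits, period, n_days) {
  states <- period_states(period)
  S <- length(states)
  days <- 0:(n_days - 1)
  p_death <- .daily_p(fits$death, days)
  r_death <- -log(1 - pmin(p_death, 1 - 1e-15))

  M <- array(0, dim = c(S, S, n_days), dimnames = list(states, states, NULL))
  for (s in states) {
    i <- match(s, states)
    if (s == "DEAD") { M[i, i, ] <- 1; next }
    if (s %in% .DISCHARGED_STATES || is.null(fits$exits[[s]])) {
      M[i, match("DEAD", states), ] <- p_death
      M[i, i, ] <- 1 - p_death
      next
    }
    p_exit <- .daily_p(fits$exits[[s]], days)
    r_exit <- -log(1 - pmin(p_exit, 1 - 1e-15))
    r_tot <- r_death + r_exit
    p_tot <- 1 - exp(-r_tot)
    w_d <- ifelse(r_tot > 0, r_death / r_tot, 0)
    p_to_dead <- p_tot * w_d
    p_to_exit <- p_tot * (1 - w_d)
    dmix <- fits$destinations[[s]]
    for (d in names(dmix))
      M[i, match(d, states), ] <- p_to_exit * dmix[[d]]
    M[i, match("DEAD", states), ] <- p_to_dead
    M[i, i, ] <- 1 - p_to_dead - p_to_exit
  }

  init <- stats::setNames(numeric(S), states)
  init[names(fits$init)] <- fits$init
  structure(list(states = states, matrices = M, init = init,
                 period = period, fits = fits, n_days = n_days),
            class = "transition_schedule")
}

#' Validate a transition schedule
#'
#' Checks non-negative entries, row sums of 1 (within `tol`) and that the
#' `DEAD` row is the unit vector, for every daily matrix.
#'
#' @param schedule A `transition_schedule`.
#' @param tol Row-sum tolerance.
#' @return `schedule`, invisibly.
#' @export
validate_schedule <- function(schedule, tol = 1e-9) {
  M <- schedule$matrices
  if (any(M < -tol)) stop("validation error: negative transition probability")
  rs <- apply(M, c(1, 3), sum)
  if (any(abs(rs - 1) > tol))
    stop("validation error: non-stochastic row (max |sum - 1| = ",
         format(max(abs(rs - 1))), ")")
  idead <- match("DEAD", schedule$states)
  if (any(M[idead, idead, ] != 1))
    stop("validation error: DEAD must be absorbing")
  invisible(schedule)
}

#' Rescale the 30-day death hazard to hit a cumulative-mortality target
#'
#' Scales every into-`DEAD` entry of the daily matrices for days 0-29 by a
#' single factor, returning the freed probability mass to each source
#' state's diagonal, with the factor chosen by bisection so that cumulative
#' `DEAD` occupancy at cycle 30 falls by exactly `pp` percentage points of
#' the cohort. Hazards from day 30 onwards are unchanged, so the hazard
#' shape within the first month is preserved. `method = "subtract"` removes
#' a constant amount from each day's into-`DEAD` entries instead of scaling
#' them (flattening rather than preserving the hazard shape); entries are
#' floored at zero and the daily amount is again found by bisection.
#'
#' @param schedule A `transition_schedule`.
#' @param pp Percentage points of the cohort (0 leaves the schedule
#'   untouched, bit for bit).
#' @param method `"scale"` or `"subtract"`.
#' @return The adjusted `transition_schedule`.
#' @export
apply_mortality_adjustment <- function(schedule, pp,
                                       method = c("scale", "subtract")) {
  method <- match.arg(method)
  if (pp < 0) stop("pp must be >= 0")
  if (pp == 0) return(schedule)
  idead <- match("DEAD", schedule$states)
  horizon <- min(30L, schedule$n_days)

  dead_at_30 <- function(M) {
    occ <- schedule$init
    for (d in seq_len(horizon)) occ <- as.vector(occ %*% M[, , d])
    occ[idead]
  }
  adjust <- function(x) {
    # x is the scaling factor ("scale") or the daily subtraction ("subtract")
    M <- schedule$matrices
    for (d in seq_len(horizon)) {
      old <- M[, idead, d]
      new <- if (method == "scale") old * x else pmax(old - x, 0)
      new[idead] <- 1
      M[, idead, d] <- new
      diag(M[, , d]) <- diag(M[, , d]) + (old - new)
      M[idead, idead, d] <- 1           # DEAD stays absorbing
      M[idead, -idead, d] <- 0
    }
    M
  }
  base <- dead_at_30(schedule$matrices)
  target <- base - pp / 100
  if (target < 0)
    stop("infeasibility error: pp = ", pp,
         " exceeds baseline cumulative mortality at day 30 (",
         signif(100 * base, 4), "%)")
  zero_deaths <- if (method == "scale") 0 else max(schedule$matrices[, idead,
                                                  seq_len(horizon)])
  if (dead_at_30(adjust(zero_deaths)) > target)
    stop("infeasibility error: target mortality unreachable with method '",
         method, "'")
  # bisection: deaths decrease in x under "subtract", increase under "scale"
  lo <- 0; hi <- if (method == "scale") 1 else zero_deaths
  for (it in 1:70) {
    mid <- (lo + hi) / 2
    high_side <- dead_at_30(adjust(mid)) > target
    if (method == "scale") { if (high_side) hi <- mid else lo <- mid }
    else { if (high_side) lo <- mid else hi <- mid }
  }
  schedule$matrices <- adjust((lo + hi) / 2)
  schedule$mortality_adjustment <- list(pp = pp, value = (lo + hi) / 2,
                                        method = method)
  schedule
}

#' Rescale stroke-unit exit times to cut the mean stay
#'
#' Rescales the exit-time Weibull scale of the designated wards so that the
#' implied mean stay `lambda * Gamma(1 + 1/k)` drops by `days`, then
#' rebuilds the daily matrices. Any mortality adjustment must be re-applied
#' afterwards (as [build_schedule()] does).
#'
#' @param schedule A `transition_schedule`.
#' @param days Days to remove from the mean stay.
#' @param wards Ward names; defaults to the schedule's adjustment spec.
#' @return A rebuilt `transition_schedule`.
#' @export
apply_los_adjustment <- function(schedule, days, wards = NULL) {
  if (days < 0) stop("days must be >= 0")
  if (days == 0) return(schedule)
  if (is.null(wards)) wards <- schedule$adjustments$su_wards
  fits <- .reduce_los(schedule$fits, days, wards)
  out <- .assemble_schedule(fits, schedule$period, schedule$n_days)
  out$adjustments <- schedule$adjustments
  out
}

#' Propagate a cohort through a transition schedule
#'
#' Deterministic cohort propagation: `occupancy(cycle + 1) =
#' occupancy(cycle) %*% matrix(cycle)`, starting from the schedule's
#' first-admission-ward distribution (or `init`). Conservation of the
#' cohort and monotonicity of `DEAD` occupancy are asserted every cycle.
#'
#' @param schedule A validated `transition_schedule`.
#' @param cohort_size Number of patients (default 6438).
#' @param init Optional initial distribution (sums to 1) over the states.
#' @return A `cohort_trace`: `occupancy` ((n_days + 1) x S matrix, cycle 0
#'   first), `states`, `cohort_size`, `cycle_days = 1`.
#' @export
run_cohort <- function(schedule, cohort_size = 6438, init = NULL) {
  stopifnot(cohort_size > 0)
  validate_schedule(schedule)
  if (is.null(init)) init <- schedule$init
  .assert_mixture(init, "init", tol = 1e-6)
  S <- length(schedule$states)
  n <- schedule$n_days
  occ <- matrix(0, n + 1, S, dimnames = list(NULL, schedule$states))
  occ[1, ] <- cohort_size * init
  idead <- match("DEAD", schedule$states)
  for (d in seq_len(n)) {
    occ[d + 1, ] <- occ[d, ] %*% schedule$matrices[, , d]
    if (abs(sum(occ[d + 1, ]) - cohort_size) > 1e-6)
      stop("conservation violated at cycle ", d)
    if (occ[d + 1, idead] < occ[d, idead] - 1e-9)
      stop("DEAD occupancy decreased at cycle ", d)
  }
  structure(list(occupancy = occ, states = schedule$states,
                 cohort_size = cohort_size, cycle_days = 1,
                 period = schedule$period),
            class = "cohort_trace")
}

#' Export a cohort trace as a cycle-by-state table
#'
#' @param trace A `cohort_trace`.
#' @param path Optional CSV path; when given the table is also written.
#' @return A `data.frame` with a `cycle` column followed by one column per
#'   state (fixed canonical order).
#' @export
trace_table <- function(trace, path = NULL) {
  df <- data.frame(cycle = seq_len(nrow(trace$occupancy)) - 1L,
                   trace$occupancy, check.names = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
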