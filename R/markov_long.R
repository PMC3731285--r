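#' Discounting specification
#'
#' @param annual_rate Annual discount rate (default 0.035, the UK health
#'   technology appraisal reference rate). Time origin is the model start.
#' @return A `discount_spec` list.
#' @export
discount_spec <- function(annual_rate = 0.035) {
  if (annual_rate < 0) stop("annual_rate must be >= 0")
  structure(list(annual_rate = annual_rate), class = "discount_spec")
}

#' Discount factor at a given day
#'
#' `factor = (1 + rate)^(-day / 365.25)`.
#'
#' @param spec A [discount_spec()] (or a bare rate).
#' @param day Day(s) from the model start; must be >= 0.
#' @return Factors in (0, 1\].
#' @export
discount_factor <- function(spec, day) {
  rate <- if (inherits(spec, "discount_spec")) spec$annual_rate else spec
  if (any(day < 0)) stop("day must be >= 0")
  (1 + rate)^(-day / 365.25)
}

#' Default long-run transition matrix (stand-in values)
#'
#' A single 90-day-cycle row-stochastic matrix over the residence/disability
#' states, used for every cycle and both periods unless overridden. The
#' values are calibrated placeholder assumptions, not published estimates:
#' per-cycle mortality rises with dependency (about 4.6%, 7.8%, 13% and
#' 18% per year across the home-independent, home-moderate, home-dependent
#' and institutional states) and there is a mild drift toward dependency.
#' Ship-your-own values via the run configuration.
#'
#' @return A 5 x 5 matrix with `LONG_STATES` dimnames.
#' @export
default_long_transitions <- function() {
  m <- rbind(
    HOME_INDEPENDENT   = c(0.9610, 0.0200, 0.0030, 0.0040, 0.0120),
    HOME_MODERATE      = c(0.0100, 0.9350, 0.0250, 0.0100, 0.0200),
    HOME_DEPENDENT     = c(0.0000, 0.0100, 0.9150, 0.0400, 0.0350),
    INSTITUTIONAL_CARE = c(0.0000, 0.0000, 0.0000, 0.9500, 0.0500),
    DEAD               = c(0.0000, 0.0000, 0.0000, 0.0000, 1.0000))
  colnames(m) <- LONG_STATES
  m
}

.validate_long_matrix <- function(m, tol = 1e-9) {
  if (!all(dim(m) == c(5, 5))) stop("long-run matrix must be 5 x 5")
  if (any(m < 0)) stop("validation error: negative transition probability")
  if (any(abs(rowSums(m) - 1) > tol))
    stop("validation error: long-run matrix rows must sum to 1")
  if (any(m[5, ] != c(0, 0, 0, 0, 1)))
    stop("validation error: DEAD row must be the unit vector")
  invisible(m)
}

#' Allocate 90-day survivors to the long-run states
#'
#' Survivors of the short-run trace at cycle 90 are mapped to the long-run
#' state space: patients at home (with or without early supported
#' discharge) are split across the three home disability bands by the
#' 90-day Barthel mixture; nursing-home patients enter institutional care;
#' patients still in hospital follow `inpatient_rule` - institutional care
#' by default, or the home bands under the discharged-to-home scenario.
#'
#' @param trace A short-run `cohort_trace` reaching cycle 90.
#' @param barthel_mix Length-3 mixture (independent, moderate, dependent)
#'   over the home bands; must sum to 1.
#' @param inpatient_rule `"institutional"` or `"home"`.
#' @return Named occupancy vector over `LONG_STATES` (persons); total equals
#'   the survivors in the trace's final cycle.
#' @export
seed_from_short_run <- function(trace, barthel_mix,
                                inpatient_rule = c("institutional", "home")) {
  stopifnot(inherits(trace, "cohort_trace"))
  inpatient_rule <- match.arg(inpatient_rule)
  .assert_mixture(barthel_mix, "barthel_mix")
  final <- trace$occupancy[nrow(trace$occupancy), ]
  home <- sum(final[intersect(c("HOME", "HOME_ESD"), names(final))])
  nh <- sum(final[intersect("NURSING_HOME", names(final))])
  inpatient <- sum(final[intersect(.INPATIENT_STATES, names(final))])
  out <- stats::setNames(numeric(5), LONG_STATES)
  if (inpatient_rule == "home") { home <- home + inpatient; inpatient <- 0 }
  out[1:3] <- home * barthel_mix
  out["INSTITUTIONAL_CARE"] <- nh + inpatient
  out
}

#' Empirical 90-day Barthel band mixture of a register
#'
#' @param register A register `data.frame`.
#' @return Length-3 mixture over (independent, moderate, dependent) among
#'   patients with a recorded 90-day Barthel score.
#' @export
barthel_mixture <- function(register) {
  b <- register$barthel_90d
  b <- b[!is.na(b)]
  if (!length(b)) stop("no 90-day Barthel scores in register")
  band <- factor(barthel_band_of(b),
                 levels = c("HOME_INDEPENDENT", "HOME_MODERATE", "HOME_DEPENDENT"))
  as.vector(table(band)) / length(b)
}

#' Propagate the long-run cohort over 90-day cycles
#'
#' @param init Named occupancy vector over `LONG_STATES` (persons).
#' @param transitions A single 5 x 5 matrix (reused each cycle) or a list of
#'   `n_cycles` matrices.
#' @param n_cycles Number of 90-day cycles (default 40, about 10 years).
#' @return A `cohort_trace` with `cycle_days = 90`; cycle 0 is the 90-day
#'   point of the short-run model.
#' @export
run_long_cohort <- function(init, transitions, n_cycles = 40L) {
  if (is.matrix(transitions)) transitions <- rep(list(transitions), n_cycles)
  if (length(transitions) != n_cycles)
    stop("need one transition matrix per cycle (or a single matrix)")
  lapply(transitions, .validate_long_matrix)
  init <- init[LONG_STATES]
  total <- sum(init)
  occ <- matrix(0, n_cycles + 1, 5, dimnames = list(NULL, LONG_STATES))
  occ[1, ] <- init
  for (cy in seq_len(n_cycles)) {
    occ[cy + 1, ] <- occ[cy, ] %*% transitions[[cy]]
    if (abs(sum(occ[cy + 1, ]) - total) > 1e-6)
      stop("conservation violated at cycle ", cy)
    if (occ[cy + 1, "DEAD"] < occ[cy, "DEAD"] - 1e-9)
      stop("DEAD occupancy decreased at cycle ", cy)
  }
  structure(list(occupancy = occ, states = LONG_STATES,
                 cohort_size = total, cycle_days = 90),
            class = "cohort_trace")
}
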