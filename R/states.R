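#' Health states of the admission-to-90-day model
#'
#' The short-run cohort model runs on ward-type and discharge-location states.
#' Inpatient states are hospital wards; discharged states are residences after
#' leaving hospital; `DEAD` is absorbing. The hyper-acute stroke unit (`HASU`)
#' exists only in the reconfigured ("after") pathway; the acute stroke unit
#' (`ASU`) and dedicated stroke-rehabilitation ward exist only in the previous
#' ("before") pathway.
#'
#' @format A character vector of state names in canonical order.
#' @export
SHORT_STATES <- c("HASU", "ASU", "SU", "STROKE_REHAB", "MEDICAL", "SURGICAL",
                  "ICU", "HOME", "HOME_ESD", "NURSING_HOME", "DEAD")

#' Residence/disability states of the 90-day-to-10-year model
#'
#' Home states are disability bands on the Barthel index (0-20 scale):
#' independent 15-20, moderate 10-14, dependent 0-9.
#'
#' @format A character vector of state names in canonical order.
#' @export
LONG_STATES <- c("HOME_INDEPENDENT", "HOME_MODERATE", "HOME_DEPENDENT",
                 "INSTITUTIONAL_CARE", "DEAD")

.INPATIENT_STATES  <- c("HASU", "ASU", "SU", "STROKE_REHAB", "MEDICAL",
                        "SURGICAL", "ICU")
.DISCHARGED_STATES <- c("HOME", "HOME_ESD", "NURSING_HOME")

#' Classify a short-run health state
#'
#' @param state Character vector of state names.
#' @return `"inpatient"`, `"discharged"` or `"absorbing"` for each state.
#' @export
state_kind <- function(state) {
  stopifnot(all(state %in% SHORT_STATES))
  ifelse(state == "DEAD", "absorbing",
         ifelse(state %in% .INPATIENT_STATES, "inpatient", "discharged"))
}

#' Short-run states permitted in a given period
#'
#' @param period `"before"` or `"after"`.
#' @return Character vector of permitted state names, canonical order.
#' @export
period_states <- function(period) {
  period <- match.arg(period, c("before", "after"))
  drop <- if (period == "before") "HASU" else c("ASU", "STROKE_REHAB")
  setdiff(SHORT_STATES, drop)
}

#' Barthel-index bands defining the long-run home states
#'
#' @return Named list of inclusive `c(lo, hi)` integer bounds partitioning
#'   the 0-20 Barthel range.
#' @export
barthel_bands <- function() {
  list(HOME_INDEPENDENT = c(15L, 20L),
       HOME_MODERATE    = c(10L, 14L),
       HOME_DEPENDENT   = c(0L, 9L))
}

#' Map Barthel scores to long-run home states
#'
#' @param score Integer Barthel scores in \[0, 20\].
#' @return Character vector of home-state names.
#' @export
barthel_band_of <- function(score) {
  if (any(score < 0 | score > 20, na.rm = TRUE))
    stop("Barthel scores must lie in [0, 20]")
  ifelse(score >= 15, "HOME_INDEPENDENT",
         ifelse(score >= 10, "HOME_MODERATE", "HOME_DEPENDENT"))
}
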