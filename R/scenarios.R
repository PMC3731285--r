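#' Built-in deterministic scenario battery
#'
#' Each scenario is a named configuration override applied to the model
#' bundle before a deterministic run. Magnitudes not determined by the
#' analysis itself (stroke-mimic fraction, hyper-acute-unit length-of-stay
#' reduction, intensive-care length-of-stay inflation) are documented
#' assumptions.
#'
#' @return Named list of scenarios, each `list(label, modify)` where
#'   `modify` maps a `model_bundle` to a modified bundle.
#' @export
default_scenarios <- function() {
  list(
    central = list(
      label = "Central estimate",
      modify = identity),
    unadjusted = list(
      label = "Unadjusted for national trends in mortality and LOS in stroke units",
      modify = function(b) {
        b$adjustments$mortality_enabled <- FALSE
        b$adjustments$los_enabled <- FALSE
        b
      }),
    adjust_mortality_only = list(
      label = "Adjusted for national trends in mortality but not LOS in stroke units",
      modify = function(b) { b$adjustments$los_enabled <- FALSE; b }),
    adjust_los_only = list(
      label = "Adjusted for national trends in LOS in stroke units but not mortality",
      modify = function(b) { b$adjustments$mortality_enabled <- FALSE; b }),
    stroke_mimics = list(
      label = "Adjustment for stroke mimics",
      modify = function(b) { b$mimic_fraction <- 0.10; b }),
    reduced_hasu_los = list(
      label = "Reduced length of stay in HASU",
      modify = function(b) {
        b$fits$after$exits$HASU$scale <- b$fits$after$exits$HASU$scale * 0.8
        b
      }),
    hasu_cost_up_25 = list(
      label = "Increase unit cost per day in HASU by 25%",
      modify = function(b) {
        b$costs$daily["HASU"] <- b$costs$daily["HASU"] * 1.25
        b
      }),
    icu_los_unadjusted = list(
      label = "Unadjusted length of stay in ICU",
      modify = function(b) {
        for (p in c("before", "after"))
          if (!is.null(b$fits[[p]]$exits$ICU))
            b$fits[[p]]$exits$ICU$scale <- b$fits[[p]]$exits$ICU$scale * 1.5
        b
      }),
    adjusted_neurosurgery = list(
      label = "Adjusted neurosurgery rates",
      modify = function(b) {
        i <- b$costs$oneoff$item == "neurosurgery"
        b$costs$oneoff$prob_before[i] <- b$costs$oneoff$prob_after[i]
        b
      }),
    nhs_only = list(
      label = "NHS costs only",
      modify = function(b) { b$costs$perspective <- "NHS-only"; b }),
    inpatients_home_at_90d = list(
      label = "Patients in hospital at three months discharged to home",
      modify = function(b) { b$inpatient_rule <- "home"; b })
  )
}

#' Run the deterministic scenario battery
#'
#' One row per scenario and horizon, with the incremental-result columns in
#' reporting order: difference in total costs, difference in total deaths,
#' incremental cost per death averted, difference in total QALYs,
#' incremental cost per QALY gained, dominance label. ICER columns are `NA`
#' where dominance makes them undefined (and the death ICER is not defined
#' at the 10-year horizon, where deaths are not an endpoint).
#'
#' @param bundle A `model_bundle`.
#' @param scenarios Named scenario list ([default_scenarios()]) or a
#'   character vector of built-in scenario names.
#' @return A `data.frame` of scenario results.
#' @export
run_scenarios <- function(bundle, scenarios = default_scenarios()) {
  if (is.character(scenarios)) {
    all_s <- default_scenarios()
    unknown <- setdiff(scenarios, names(all_s))
    if (length(unknown))
      stop("unknown scenario(s): ", paste(unknown, collapse = ", "),
           "; available: ", paste(names(all_s), collapse = ", "))
    scenarios <- all_s[scenarios]
  }
  rows <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    res <- run_model(sc$modify(bundle))
    for (h in c("90d", "10y")) {
      r <- if (h == "90d") res$result_90d else res$result_10y
      rows[[length(rows) + 1]] <- data.frame(
        scenario = nm, label = sc$label, horizon = h,
        d_cost = r$d_cost, d_deaths = r$d_deaths,
        icer_per_death_averted =
          if (h == "90d") r$icer_per_death_averted else NA_real_,
        d_qalys = r$d_qalys, icer_per_qaly = r$icer_per_qaly,
        dominance = r$dominance, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
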