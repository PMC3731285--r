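#' Default run configuration
#'
#' The single structured configuration object behind the command-style
#' entry points. Fields whose defaults are documented stand-ins for
#' unpublished supplementary values (unit costs, long-run transitions,
#' Barthel mixtures, scenario magnitudes) are listed in
#' `$assumption_fields` so downstream reports can flag them.
#'
#' @param seed Master seed; module sub-streams (generator arms, PSA) are
#'   derived from it deterministically.
#' @return A nested configuration list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort_size = 6438,
    output_dir = "strokecea-output",
    register_files = list(before = "register_before.csv",
                          after = "register_after.csv"),
    generator = list(before = list(), after = list()),   # overrides
    age_covariate = TRUE,
    adjustments = list(mortality_pp_30d = 2.4, su_los_days = 5.0,
                       mortality_enabled = TRUE, los_enabled = TRUE,
                       su_wards = "STROKE_REHAB", mortality_method = "scale"),
    perspective = "NHS+PSS",
    discount_rate = 0.035,
    inpatient_rule = "institutional",
    psa = list(n_draws = 10000L, cost_se_frac = 0.2, long_ess = 200),
    scenarios = names(default_scenarios()),
    assumption_fields = c("costs.daily", "costs.cycle", "costs.oneoff.unit_cost",
                          "long_transitions", "barthel_mix",
                          "scenario.stroke_mimics.fraction",
                          "scenario.reduced_hasu_los.factor",
                          "scenario.icu_los_unadjusted.factor")),
    class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown top-level fields are rejected with their field path; supplied
#' fields override [default_run_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("schema violation at field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, raw)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A `run_config`.
#' @return `cfg`, invisibly, or an error naming the offending field path.
#' @export
validate_run_config <- function(cfg) {
  chk <- function(ok, path_, msg)
    if (!ok) stop("schema violation at '", path_, "': ", msg, call. = FALSE)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed", "integer required")
  chk(is.numeric(cfg$cohort_size) && cfg$cohort_size > 0, "cohort_size", "> 0 required")
  chk(cfg$perspective %in% c("NHS+PSS", "NHS-only"), "perspective",
      "must be 'NHS+PSS' or 'NHS-only'")
  chk(is.numeric(cfg$discount_rate) && cfg$discount_rate >= 0,
      "discount_rate", ">= 0 required")
  chk(cfg$inpatient_rule %in% c("institutional", "home"), "inpatient_rule",
      "must be 'institutional' or 'home'")
  chk(cfg$adjustments$mortality_pp_30d >= 0, "adjustments.mortality_pp_30d",
      ">= 0 required")
  chk(cfg$adjustments$su_los_days >= 0, "adjustments.su_los_days", ">= 0 required")
  chk(cfg$psa$n_draws >= 2, "psa.n_draws", ">= 2 required")
  invisible(cfg)
}

# write a reproducibility manifest next to each command's outputs
.write_manifest <- function(out_dir, cfg, files, command) {
  tmp <- tempfile()
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(command = command,
                   config_md5 = unname(tools::md5sum(tmp)),
                   seed = cfg$seed,
                   package = "strokecea",
                   package_version = as.character(utils::packageVersion("strokecea")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   outputs = files)
  unlink(tmp)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.adjustments_from_config <- function(cfg) {
  a <- cfg$adjustments
  adjustment_spec(a$mortality_pp_30d, a$su_los_days, a$mortality_enabled,
                  a$los_enabled, a$su_wards, a$mortality_method)
}

#' Generate the synthetic registers
#'
#' Writes one register CSV per period into the output directory, using
#' per-arm sub-seeds derived from the master seed, plus a run manifest.
#'
#' @param cfg A `run_config`.
#' @return Named paths of the written registers, invisibly.
#' @export
cmd_simulate <- function(cfg = default_run_config()) {
  validate_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (period in c("before", "after")) {
    gc <- do.call(default_generator_config,
                  c(list(period = period,
                         seed = .sub_seed(cfg$seed, paste0("generator_", period))),
                    cfg$generator[[period]]))
    reg <- generate_cohort(gc)
    path <- file.path(cfg$output_dir, cfg$register_files[[period]])
    write_register(reg, path)
    paths[period] <- path
  }
  .write_manifest(cfg$output_dir, cfg, as.list(paths), "simulate")
  invisible(paths)
}

#' Serialize pathway fits to JSON
#'
#' @param pf A `pathway_fits` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_fits <- function(pf, path) {
  ser <- list(period = pf$period,
              death = .ser_fit(pf$death),
              exits = lapply(pf$exits, .ser_fit),
              destinations = lapply(pf$destinations, as.list),
              dest_counts = lapply(pf$dest_counts, as.list),
              init = as.list(pf$init), init_counts = as.list(pf$init_counts))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.ser_fit <- function(f) {
  f$covariance <- list(names = rownames(f$covariance),
                       values = as.vector(f$covariance))
  unclass(f)
}

.deser_fit <- function(f) {
  nm <- unlist(f$covariance$names)
  f$covariance <- matrix(unlist(f$covariance$values), length(nm), length(nm),
                         dimnames = list(nm, nm))
  f$coefficients <- if (length(f$coefficients)) unlist(f$coefficients) else NULL
  structure(f, class = "survival_fit")
}

#' Read pathway fits written by [write_pathway_fits()]
#'
#' @param path JSON path.
#' @return A `pathway_fits` object.
#' @export
read_pathway_fits <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(list(period = raw$period,
                 death = .deser_fit(raw$death),
                 exits = lapply(raw$exits, .deser_fit),
                 destinations = lapply(raw$destinations, unlist),
                 dest_counts = lapply(raw$dest_counts, unlist),
                 init = unlist(raw$init), init_counts = unlist(raw$init_counts)),
            class = "pathway_fits")
}

#' Fit the pathway models from the simulated registers
#'
#' Requires the register files written by [cmd_simulate()]; writes one
#' pathway-fit JSON per period.
#'
#' @param cfg A `run_config`.
#' @return Named paths of the fit files, invisibly.
#' @export
cmd_fit <- function(cfg = default_run_config()) {
  validate_run_config(cfg)
  paths <- character()
  for (period in c("before", "after")) {
    reg_path <- file.path(cfg$output_dir, cfg$register_files[[period]])
    if (!file.exists(reg_path))
      stop("missing upstream register '", reg_path, "'; run cmd_simulate first")
    reg <- read_register(reg_path)
    pf <- fit_pathway(reg, age_covariate = cfg$age_covariate)
    path <- file.path(cfg$output_dir, paste0("fits_", period, ".json"))
    write_pathway_fits(pf, path)
    paths[period] <- path
  }
  .write_manifest(cfg$output_dir, cfg, as.list(paths), "fit")
  invisible(paths)
}

.bundle_from_config <- function(cfg, fits = NULL) {
  if (is.null(fits)) {
    fits <- list()
    for (period in c("before", "after")) {
      fp <- file.path(cfg$output_dir, paste0("fits_", period, ".json"))
      if (!file.exists(fp))
        stop("missing upstream fits '", fp, "'; run cmd_fit first")
      fits[[period]] <- read_pathway_fits(fp)
    }
  }
  bmix <- list(before = c(0.45, 0.22, 0.33), after = c(0.55, 0.22, 0.23))
  for (period in c("before", "after")) {
    rp <- file.path(cfg$output_dir, cfg$register_files[[period]])
    if (file.exists(rp)) {
      reg <- try(read_register(rp), silent = TRUE)
      if (!inherits(reg, "try-error") && any(!is.na(reg$barthel_90d)))
        bmix[[period]] <- barthel_mixture(reg)
    }
  }
  model_bundle(fits = fits,
               adjustments = .adjustments_from_config(cfg),
               costs = default_cost_schedule(cfg$perspective),
               barthel_mix = bmix,
               inpatient_rule = cfg$inpatient_rule,
               discount = discount_spec(cfg$discount_rate),
               cohort_size = cfg$cohort_size)
}

#' Run the deterministic before/after comparison
#'
#' Requires the fit files written by [cmd_fit()]. Writes the 90-day and
#' 10-year incremental reports (JSON), the four cohort traces (CSV) and a
#' manifest.
#'
#' @param cfg A `run_config`.
#' @return The [run_model()] result, invisibly.
#' @export
cmd_run <- function(cfg = default_run_config()) {
  validate_run_config(cfg)
  bundle <- .bundle_from_config(cfg)
  res <- run_model(bundle)
  out <- cfg$output_dir
  files <- list()
  for (period in c("before", "after")) {
    files[[paste0("trace_short_", period)]] <-
      trace_table(res[[period]]$trace_short,
                  file.path(out, paste0("trace_short_", period, ".csv")))
    files[[paste0("trace_long_", period)]] <-
      trace_table(res[[period]]$trace_long,
                  file.path(out, paste0("trace_long_", period, ".csv")))
  }
  report <- list(
    horizon_90d = res$result_90d[c("d_cost", "d_deaths", "d_qalys",
                                   "icer_per_death_averted", "icer_per_qaly",
                                   "dominance")],
    horizon_10y = res$result_10y[c("d_cost", "d_qalys", "icer_per_qaly",
                                   "dominance")],
    per_arm = list(
      before = res$before$arm_90d[c("total_cost", "per_patient_cost",
                                    "total_qalys", "deaths")],
      after = res$after$arm_90d[c("total_cost", "per_patient_cost",
                                  "total_qalys", "deaths")]),
    assumption_fields = cfg$assumption_fields)
  jsonlite::write_json(report, file.path(out, "report_deterministic.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out, cfg, c("report_deterministic.json",
                              sort(names(files))), "run")
  invisible(res)
}

#' Run the probabilistic sensitivity analysis
#'
#' Writes the per-draw increments (CSV), acceptability curves for both
#' horizons (CSV) and a summary (JSON).
#'
#' @param cfg A `run_config`.
#' @return The `psa_result`, invisibly.
#' @export
cmd_psa <- function(cfg = default_run_config()) {
  validate_run_config(cfg)
  bundle <- .bundle_from_config(cfg)
  spec <- psa_spec(n_draws = cfg$psa$n_draws,
                   seed = .sub_seed(cfg$seed, "psa"),
                   cost_se_frac = cfg$psa$cost_se_frac,
                   long_ess = cfg$psa$long_ess)
  res <- run_psa(bundle, spec)
  out <- cfg$output_dir
  utils::write.csv(res$draws, file.path(out, "psa_draws.csv"), row.names = FALSE)
  for (h in c("90d", "10y"))
    utils::write.csv(ceac(res, horizon = h),
                     file.path(out, paste0("ceac_", h, ".csv")),
                     row.names = FALSE)
  summary <- list(means = as.list(res$means),
                  ci = list(low = as.list(res$ci[1, ]),
                            high = as.list(res$ci[2, ])),
                  n_draws = nrow(res$draws), n_failed = res$n_failed)
  jsonlite::write_json(summary, file.path(out, "psa_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out, cfg, list("psa_draws.csv", "ceac_90d.csv",
                                 "ceac_10y.csv", "psa_summary.json"), "psa")
  invisible(res)
}

#' Run the deterministic scenario battery
#'
#' @param cfg A `run_config`.
#' @return The scenario table, invisibly; written as
#'   `scenarios.csv` in the output directory.
#' @export
cmd_scenarios <- function(cfg = default_run_config()) {
  validate_run_config(cfg)
  bundle <- .bundle_from_config(cfg)
  tab <- run_scenarios(bundle, cfg$scenarios)
  utils::write.csv(tab, file.path(cfg$output_dir, "scenarios.csv"),
                   row.names = FALSE)
  .write_manifest(cfg$output_dir, cfg, list("scenarios.csv"), "scenarios")
  invisible(tab)
}
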