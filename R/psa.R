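#' Probabilistic sensitivity analysis specification
#'
#' Distribution families follow standard health-economics practice:
#' survival parameters are multivariate normal on the log scale (shape and
#' scale stay positive) using each fit's covariance; destination, initial
#' and long-run transition mixtures are Dirichlet with concentrations given
#' by observed counts (or mixture x effective sample size); one-off event
#' probabilities are beta with the period's sample size; unit costs are
#' gamma with a fixed coefficient of variation. Any component group can be
#' frozen at its point estimate.
#'
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed for the draw stream.
#' @param cost_se_frac Coefficient of variation of unit costs (gamma).
#' @param ess Named effective sample sizes `c(before = , after = )` for
#'   event-probability betas.
#' @param long_ess Effective sample size behind each long-run matrix row.
#' @param frozen Character subset of
#'   `c("survival", "mixtures", "event_probs", "costs", "long_transitions")`
#'   held at the point estimate.
#' @return A `psa_spec` list.
#' @export
psa_spec <- function(n_draws = 10000L, seed = 1L, cost_se_frac = 0.2,
                     ess = c(before = 307, after = 3156), long_ess = 200,
                     frozen = character()) {
  if (n_draws < 2) stop("configuration error: n_draws must be >= 2")
  .assert_pos(cost_se_frac, "cost_se_frac")
  .assert_pos(long_ess, "long_ess")
  bad <- setdiff(frozen, c("survival", "mixtures", "event_probs", "costs",
                           "long_transitions"))
  if (length(bad))
    stop("configuration error: unknown frozen group(s): ",
         paste(bad, collapse = ", "))
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 cost_se_frac = cost_se_frac, ess = ess, long_ess = long_ess,
                 frozen = frozen),
            class = "psa_spec")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

.perturb_fit <- function(fit) {
  V <- fit$covariance[c("log_scale", "log_shape"),
                      c("log_scale", "log_shape"), drop = FALSE]
  if (all(V == 0) || anyNA(V)) return(fit)
  # draws on (log scale, log lambda) keep both parameters positive
  L <- tryCatch(chol(V + diag(1e-12, 2)), error = function(e) NULL)
  if (is.null(L)) return(fit)
  z <- as.vector(stats::rnorm(2) %*% L)
  fit$scale <- exp(log(fit$scale) + z[1])
  fit$shape <- exp(log(fit$shape) + z[2])
  fit
}

#' Draw one perturbed parameter set
#'
#' Returns a perturbed copy of the bundle according to the spec's
#' distributions; frozen groups are returned unchanged. Consumes random
#' numbers from the current stream.
#'
#' @param bundle A `model_bundle`.
#' @param spec A [psa_spec()].
#' @return A perturbed `model_bundle`.
#' @export
perturb_bundle <- function(bundle, spec) {
  fz <- spec$frozen
  for (period in c("before", "after")) {
    pf <- bundle$fits[[period]]
    if (!"survival" %in% fz) {
      pf$death <- .perturb_fit(pf$death)
      pf$exits <- lapply(pf$exits, .perturb_fit)
    }
    if (!"mixtures" %in% fz) {
      for (w in names(pf$destinations)) {
        a <- pf$dest_counts[[w]] + 0.5
        pf$destinations[[w]] <- stats::setNames(.rdirichlet1(a),
                                                names(pf$destinations[[w]]))
      }
      a0 <- pf$init_counts + 0.5
      pf$init <- stats::setNames(.rdirichlet1(a0), names(pf$init))
    }
    bundle$fits[[period]] <- pf
  }
  if (!"event_probs" %in% fz) {
    oo <- bundle$costs$oneoff
    for (period in c("before", "after")) {
      p <- oo[[paste0("prob_", period)]]
      n <- spec$ess[[period]]
      a <- p * n; b <- (1 - p) * n
      a[a == 0] <- 0.5; b[b == 0] <- 0.5   # guard degenerate 0/1 rates
      oo[[paste0("prob_", period)]] <- stats::rbeta(length(p), a, b)
    }
    bundle$costs$oneoff <- oo
  }
  if (!"costs" %in% fz) {
    shp <- 1 / spec$cost_se_frac^2
    perturb_cost <- function(x) ifelse(x > 0,
      stats::rgamma(length(x), shape = shp, rate = shp / pmax(x, 1e-12)), 0)
    bundle$costs$daily <- stats::setNames(perturb_cost(bundle$costs$daily),
                                          names(bundle$costs$daily))
    bundle$costs$cycle <- stats::setNames(perturb_cost(bundle$costs$cycle),
                                          names(bundle$costs$cycle))
    bundle$costs$oneoff$unit_cost <- perturb_cost(bundle$costs$oneoff$unit_cost)
  }
  if (!"long_transitions" %in% fz) {
    for (period in c("before", "after")) {
      m <- bundle$long_transitions[[period]]
      for (i in 1:4) {
        pos <- m[i, ] > 0
        m[i, pos] <- .rdirichlet1(m[i, pos] * spec$long_ess + 0.5)
      }
      bundle$long_transitions[[period]] <- m
    }
  }
  bundle
}

#' Draw a sequence of parameter sets
#'
#' @param spec A [psa_spec()].
#' @param bundle A `model_bundle`.
#' @param n Number of draws (defaults to `spec$n_draws`).
#' @return A list of perturbed `model_bundle`s; reproducible given
#'   `spec$seed`.
#' @export
draw_parameters <- function(spec, bundle, n = spec$n_draws) {
  set.seed(spec$seed)
  lapply(seq_len(n), function(i) perturb_bundle(bundle, spec))
}

#' Run the probabilistic sensitivity analysis
#'
#' Per draw: perturb every unfrozen parameter group, rebuild both arms'
#' schedules, run both Markov models, accrue, and record the increments at
#' both horizons. Confidence intervals are empirical 2.5/97.5 percentiles.
#' Individual draw failures are logged and excluded; more than 1% failures
#' aborts with diagnostics.
#'
#' @param bundle A `model_bundle` (must run cleanly at the point estimate).
#' @param spec A [psa_spec()].
#' @param progress Print a dot every 500 draws?
#' @return A `psa_result`: `draws` (data.frame of per-draw increments),
#'   `means`, `ci` (2.5/97.5 percentiles), `point` (deterministic result),
#'   `n_failed`, `spec`.
#' @export
run_psa <- function(bundle, spec = psa_spec(), progress = FALSE) {
  point <- run_model(bundle)     # errors here mean the point estimate is broken
  set.seed(spec$seed)
  cols <- c("d_cost_90d", "d_deaths_90d", "d_qalys_90d",
            "d_cost_10y", "d_qalys_10y")
  draws <- matrix(NA_real_, spec$n_draws, length(cols),
                  dimnames = list(NULL, cols))
  failures <- character()
  for (i in seq_len(spec$n_draws)) {
    res <- tryCatch({
      pb <- perturb_bundle(bundle, spec)
      r <- run_model(pb)
      c(r$result_90d$d_cost, r$result_90d$d_deaths, r$result_90d$d_qalys,
        r$result_10y$d_cost, r$result_10y$d_qalys)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures <- c(failures, res) else draws[i, ] <- res
    if (progress && i %% 500 == 0) cat(".")
  }
  if (length(failures) > spec$n_draws * 0.01)
    stop("PSA aborted: ", length(failures), " of ", spec$n_draws,
         " draws failed; first errors: ",
         paste(utils::head(unique(failures), 3), collapse = " | "))
  ok <- stats::complete.cases(draws)
  draws <- as.data.frame(draws[ok, , drop = FALSE])
  structure(list(draws = draws,
                 means = colMeans(draws),
                 ci = apply(draws, 2, stats::quantile,
                            probs = c(0.025, 0.975)),
                 point = point, n_failed = length(failures), spec = spec),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability that the new
#' service is cost-effective is the fraction of draws with positive net
#' monetary benefit `lambda * dQALY - dCost`. At `lambda = 0` this is the
#' fraction of cost-saving draws. The default grid spans 0-50,000 pounds
#' per QALY in steps of 1,000, covering the 20,000-30,000 NICE reference
#' range.
#'
#' @param result A `psa_result`.
#' @param thresholds Ascending grid of thresholds (pounds/QALY).
#' @param horizon `"90d"` or `"10y"`.
#' @return A data.frame with columns `threshold` and `probability`.
#' @export
ceac <- function(result, thresholds = seq(0, 50000, by = 1000),
                 horizon = c("90d", "10y")) {
  stopifnot(inherits(result, "psa_result"))
  horizon <- match.arg(horizon)
  if (length(thresholds) == 0) stop("empty threshold grid")
  if (nrow(result$draws) < 2) stop("need at least 2 draws")
  dc <- result$draws[[paste0("d_cost_", horizon)]]
  dq <- result$draws[[paste0("d_qalys_", horizon)]]
  prob <- vapply(thresholds, function(l) mean(l * dq - dc > 0), numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}
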