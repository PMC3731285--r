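#' Kaplan-Meier product-limit estimate with Greenwood intervals
#'
#' Thin, validated wrapper around [survival::survfit()] returning the
#' product-limit estimator with Greenwood-variance 95% confidence bounds
#' (linear scale, clipped to \[0, 1\]). At tied times, events are handled
#' before censorings, the standard product-limit convention.
#'
#' @param times Non-negative follow-up times (days).
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return A `km_curve` list: `event_times`, `survival`, `ci_low`, `ci_high`,
#'   `n_risk`, `n_event` (one entry per distinct event time).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("cannot estimate: empty input")
  if (length(times) != length(events)) stop("times and events lengths differ")
  if (any(times < 0)) stop("validation error: negative survival time")
  events <- as.logical(events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "plain", conf.int = 0.95)
  keep <- sf$n.event > 0
  lo <- pmax(0, sf$lower[keep]); hi <- pmin(1, sf$upper[keep])
  # Greenwood variance is undefined once S reaches 0; pin the bounds there
  lo[is.na(lo)] <- sf$surv[keep][is.na(lo)]
  hi[is.na(hi)] <- sf$surv[keep][is.na(hi)]
  structure(list(event_times = sf$time[keep],
                 survival = sf$surv[keep],
                 ci_low = lo,
                 ci_high = hi,
                 n_risk = sf$n.risk[keep],
                 n_event = sf$n.event[keep],
                 n = length(times), n_events = sum(events)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given days
#'
#' @param curve A `km_curve`.
#' @param day Days at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(curve, day) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(day, function(d) {
    i <- which(curve$event_times <= d)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

# Replace zero survival times (deaths on the admission day) by half a day:
# parametric fits need t > 0 and on a daily grid half a day is the natural
# imputation.
.halfday <- function(times) {
  times[times <= 0] <- 0.5
  times
}

#' Fit a parametric Weibull (or exponential) survival model
#'
#' Maximum-likelihood fit via [survival::survreg()], reported in the
#' proportional-hazards convention used throughout this package:
#' `S(t | x) = exp(-(t/lambda)^k * exp(x'beta))` with shape `k`, scale
#' `lambda` (days) and covariate coefficients `beta` on the log-hazard
#' scale. The covariance matrix of `(log lambda, log k, beta...)` is derived
#' from the observed information of the accelerated-failure-time fit by the
#' delta method. Fixing the shape at 1 (`fix_shape = 1`) gives the
#' exponential model, whose scale MLE is total time over total events.
#' Zero survival times are imputed as 0.5 days.
#'
#' @param times Follow-up times (days, > 0 after half-day imputation).
#' @param events Logical event indicators.
#' @param covariates Optional `data.frame` (or vector) of covariates.
#' @param fix_shape `NULL` (estimate the shape) or `1` (exponential).
#' @param period Optional period label carried into the result.
#' @return A `survival_fit` list: `family`, `shape`, `scale`,
#'   `coefficients` (log-hazard), `covariance`, `loglik`, `n`, `n_events`,
#'   `period`.
#' @export
fit_weibull <- function(times, events, covariates = NULL, fix_shape = NULL,
                        period = NA_character_) {
  events <- as.logical(events)
  if (sum(events) == 0) stop("cannot fit: no events")
  if (sum(events) < 2) stop("cannot fit: fewer than 2 events")
  times <- .halfday(times)
  if (is.null(fix_shape) && all(events) &&
      length(unique(times[events])) == 1L)
    stop("non-convergence: all events occur at a single instant")

  dat <- data.frame(.t = times, .e = events)
  form <- survival::Surv(.t, .e) ~ 1
  if (!is.null(covariates)) {
    if (!is.data.frame(covariates)) covariates <- data.frame(x = covariates)
    dat <- cbind(dat, covariates)
    form <- stats::as.formula(paste("survival::Surv(.t, .e) ~",
                                    paste(names(covariates), collapse = " + ")))
  }
  dist <- if (identical(fix_shape, 1) || identical(fix_shape, 1L))
    "exponential" else "weibull"
  fit <- withCallingHandlers(
    tryCatch(survival::survreg(form, data = dat, dist = dist),
             error = function(e) stop("non-convergence: ", conditionMessage(e),
                                      call. = FALSE)),
    warning = function(w) {
      if (grepl("converge|infinite|NaN", conditionMessage(w), ignore.case = TRUE))
        stop("non-convergence: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })

  sigma <- if (dist == "exponential") 1 else fit$scale
  mu <- unname(stats::coef(fit)[1])
  b_aft <- stats::coef(fit)[-1]
  shape <- 1 / sigma
  scale <- exp(mu)
  beta_ph <- -b_aft / sigma

  # delta method: AFT parameters (mu, b_aft..., log sigma) ->
  # (log lambda, log k, beta_ph...)
  V_aft <- stats::vcov(fit)                      # order: mu, b_aft..., Log(scale)
  p <- length(b_aft)
  npar <- nrow(V_aft)
  has_ls <- npar == p + 2                        # weibull has Log(scale) row
  J <- matrix(0, nrow = 2 + p, ncol = npar)
  J[1, 1] <- 1                                   # d log lambda / d mu
  if (has_ls) J[2, npar] <- -1                   # d log k / d log sigma
  if (p > 0) {
    for (j in seq_len(p)) {
      J[2 + j, 1 + j] <- -1 / sigma
      if (has_ls) J[2 + j, npar] <- b_aft[j] / sigma
    }
  }
  V <- J %*% V_aft %*% t(J)
  nm <- c("log_scale", "log_shape", names(b_aft))
  dimnames(V) <- list(nm, nm)

  structure(list(family = if (dist == "exponential") "exponential" else "weibull",
                 shape = unname(shape), scale = unname(scale),
                 coefficients = beta_ph, covariance = V,
                 loglik = fit$loglik[length(fit$loglik)],
                 n = length(times), n_events = sum(events),
                 period = period),
            class = "survival_fit")
}

#' Weibull survival function of a fitted model
#'
#' @param fit A `survival_fit`.
#' @param t Days.
#' @param hr Optional proportional multiplier on the cumulative hazard
#'   (e.g. a covariate hazard ratio).
#' @return `S(t) = exp(-(t/lambda)^k * hr)`.
#' @export
fit_survival <- function(fit, t, hr = 1) {
  stopifnot(inherits(fit, "survival_fit"))
  .weib_surv(t, fit$shape, fit$scale)^hr
}

#' Per-day transition probability implied by a parametric fit
#'
#' Converts a fitted Weibull hazard into the probability of the event
#' during day `day` given survival to its start:
#' `p(day) = 1 - S(day + 1) / S(day)`. Time-dependence enters through the
#' Weibull shape; a shape of 1 gives a constant daily probability
#' (exponential memorylessness). When `S(day)` underflows to zero the event
#' is certain by then and 1 is returned with a warning.
#'
#' @param fit A `survival_fit`.
#' @param day Integer day(s) >= 0 since admission.
#' @param hr Proportional hazard multiplier.
#' @return Probabilities in \[0, 1\], one per day.
#' @export
daily_transition_prob <- function(fit, day, hr = 1) {
  stopifnot(inherits(fit, "survival_fit"))
  if (any(day < 0)) stop("day must be >= 0")
  s0 <- fit_survival(fit, day, hr)
  s1 <- fit_survival(fit, day + 1, hr)
  p <- ifelse(s0 == 0, 1, 1 - s1 / s0)
  if (any(s0 == 0))
    warning("survival already 0 at requested day; transition is certain")
  pmin(pmax(p, 0), 1)
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood fit via [survival::coxph()] with Breslow handling of
#' tied event times (simple, slightly biased toward zero with heavy ties;
#' chosen so the partial likelihood matches its textbook form exactly).
#' Zero survival times are imputed as 0.5 days.
#'
#' @param times Follow-up times (days).
#' @param events Logical event indicators.
#' @param covariates `data.frame` (or vector) of covariates; each must vary.
#' @return A `cox_fit` list: `coefficients`, `hazard_ratio`, `ci_low`,
#'   `ci_high` (95%, `exp(beta +- 1.96 se)`), `se`, `loglik`, `ties`,
#'   `separation` flag, `n`, `n_events`.
#' @export
fit_cox <- function(times, events, covariates) {
  events <- as.logical(events)
  if (sum(events) < 2) stop("cannot fit: fewer than 2 events")
  if (!is.data.frame(covariates)) covariates <- data.frame(x = covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[is.finite(as.numeric(as.factor(v)))])) < 2 ||
        length(unique(v)) < 2)
      stop("non-identifiability error: covariate '", nm, "' is constant")
  }
  dat <- cbind(data.frame(.t = .halfday(times), .e = events), covariates)
  form <- stats::as.formula(paste("survival::Surv(.t, .e) ~",
                                  paste(names(covariates), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE)) {
        separation <<- TRUE
        warning("possible separation: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(coefficients = beta, hazard_ratio = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 se = se, loglik = fit$loglik[2], ties = "breslow",
                 separation = separation,
                 n = length(times), n_events = sum(events)),
            class = "cox_fit")
}

#' Serialize survival fits to JSON
#'
#' @param fits A named list of `survival_fit` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  ser <- lapply(fits, function(f) {
    f$covariance <- list(names = rownames(f$covariance),
                         values = as.vector(f$covariance))
    unclass(f)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read survival fits written by [write_fits()]
#'
#' @param path JSON path.
#' @return Named list of `survival_fit` objects.
#' @export
read_fits <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(f) {
    nm <- f$covariance$names
    V <- matrix(f$covariance$values, length(nm), length(nm),
                dimnames = list(nm, nm))
    f$covariance <- V
    f$coefficients <- unlist(f$coefficients)
    structure(f, class = "survival_fit")
  })
}
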