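# Independent oracles and small fixtures used across the suite.

# --- toy transition schedule ------------------------------------------------
# constant daily death probability from every alive state; states must
# include DEAD last
toy_schedule <- function(p_death, states = c("HOME", "DEAD"), n_days = 90L,
                         init = NULL) {
  S <- length(states)
  M <- array(0, dim = c(S, S, n_days), dimnames = list(states, states, NULL))
  idead <- match("DEAD", states)
  for (i in seq_len(S)) {
    if (i == idead) { M[i, i, ] <- 1; next }
    M[i, idead, ] <- p_death
    M[i, i, ] <- 1 - p_death
  }
  if (is.null(init)) {
    init <- stats::setNames(rep(0, S), states)
    init[1] <- 1
  }
  structure(list(states = states, matrices = M, init = init,
                 period = "before", fits = NULL, n_days = n_days,
                 adjustments = adjustment_spec()),
            class = "transition_schedule")
}

# --- microsimulation oracle -------------------------------------------------
# Individual-level walker simulation of a schedule: per cycle, walkers in
# each state are multinomially reallocated by that state's row. Returns
# occupancy counts per cycle (same shape as a cohort trace).
microsim_trace <- function(schedule, n_walkers = 1e5, seed = 1) {
  set.seed(seed)
  S <- length(schedule$states)
  counts <- stats::rmultinom(1, n_walkers, schedule$init)[, 1]
  occ <- matrix(0, schedule$n_days + 1, S,
                dimnames = list(NULL, schedule$states))
  occ[1, ] <- counts
  for (d in seq_len(schedule$n_days)) {
    nxt <- numeric(S)
    for (s in seq_len(S)) {
      if (counts[s] == 0) next
      nxt <- nxt + stats::rmultinom(1, counts[s], schedule$matrices[s, , d])[, 1]
    }
    counts <- nxt
    occ[d + 1, ] <- counts
  }
  occ
}

# --- Weibull grid-search likelihood oracle ----------------------------------
# censored Weibull log-likelihood, written out directly
weib_loglik <- function(k, l, times, events) {
  sum(events * (log(k / l) + (k - 1) * log(times / l)) - (times / l)^k)
}

# coarse-to-fine grid search over (shape, scale)
weib_grid_mle <- function(times, events, k_range = c(0.5, 3),
                          l_range = c(50, 2000), rounds = 6, n_grid = 21) {
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    ks <- seq(k_range[1], k_range[2], length.out = n_grid)
    ls <- seq(l_range[1], l_range[2], length.out = n_grid)
    ll <- outer(ks, ls, Vectorize(function(k, l) weib_loglik(k, l, times, events)))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(ks[ij[1]], ls[ij[2]])
    dk <- diff(k_range) / (n_grid - 1); dl <- diff(l_range) / (n_grid - 1)
    k_range <- c(best[1] - dk, best[1] + dk)
    l_range <- c(best[2] - dl, best[2] + dl)
  }
  stats::setNames(best, c("shape", "scale"))
}

# --- Cox partial-likelihood oracle ------------------------------------------
# Breslow partial log-likelihood for one binary/continuous covariate,
# written out directly from its definition
cox_partial_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(as.logical(events))) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# observed follow-up time / event columns of a register
register_surv <- function(reg) {
  list(time = ifelse(is.na(reg$death_day), reg$censor_day, reg$death_day),
       event = !is.na(reg$death_day))
}

# small register fixture (deterministic)
small_register <- function(n = 60, period = "after", seed = 5) {
  generate_cohort(default_generator_config(period, n_patients = n, seed = seed))
}
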