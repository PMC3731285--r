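# internal helpers shared across modules

.assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("configuration error: '%s' must be a probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

.assert_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("configuration error: '%s' must be strictly positive", name),
         call. = FALSE)
  invisible(x)
}

.assert_mixture <- function(p, name, tol = 1e-9) {
  .assert_prob(p, name)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("configuration error: '%s' must sum to 1 (got %.12g)", name, sum(p)),
         call. = FALSE)
  invisible(p)
}

# Derive a named reproducible sub-seed from a master seed; keeps results
# of independent modules (generator arms, PSA) decoupled but deterministic.
# Kept well inside 32-bit integer range.
.sub_seed <- function(seed, stream) {
  offsets <- c(generator_before = 101L, generator_after = 202L,
               psa = 303L, microsim = 404L, scenario = 505L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483587)
}

# Weibull survival S(t) = exp(-(t/scale)^shape); the convention used for
# every shape/scale pair in this package.
.weib_surv <- function(t, shape, scale) exp(-(t / scale)^shape)

# mean of a Weibull time-to-event
.weib_mean <- function(shape, scale) scale * gamma(1 + 1 / shape)
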