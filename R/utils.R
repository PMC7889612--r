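#' @importFrom rlang abort warn .data
#' @importFrom stats qnorm pnorm rnorm runif rbinom rpois quantile coef
#'   plogis qlogis binomial glm.fit p.adjust t.test sd setNames
#' @importFrom utils head
NULL

# Validate a single positive finite scalar.
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "tempbias_invalid_parameter")
  }
  invisible(x)
}

check_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s.", name,
                  if (open) "(0, 1)" else "[0, 1]"),
          class = "tempbias_invalid_parameter")
  }
  invisible(x)
}

# Seed the global RNG when a seed is supplied; simulation functions in this
# package advance the global stream, which is the usual contract for
# simulation toolkits (same seed + same config => identical output).
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("`seed` must be a single finite number.",
            class = "tempbias_invalid_parameter")
    }
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# sample() that never falls into the scalar-x gotcha.
sample_vec <- function(x, n) {
  x[sample.int(length(x), n, replace = TRUE)]
}

# Draw integer sub-seeds for reproducible nested experiments.
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

# Truncated-at-zero normal draws via inverse CDF (values stay > 0 when
# lower tail mass is removed).
rnorm_pos <- function(n, mean, sd) {
  if (any(sd < 0)) abort("negative noise SD", class = "tempbias_invalid_parameter")
  lo <- pnorm(0, mean, sd)
  u <- lo + runif(n) * (1 - lo)
  pmax(qnorm(u, mean, sd), .Machine$double.eps)
}

# Fast logistic fit of a binary outcome on a single exposure column.
# Returns the exposure coefficient and its standard error.
fit_logit <- function(x, y) {
  fit <- suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))
  if (!fit$converged) {
    abort("logistic fit failed to converge (possible separation)",
          class = "tempbias_estimation_failure")
  }
  mu <- fit$fitted.values
  if (all(mu > 1 - 1e-8) || all(mu < 1e-8)) {
    abort("degenerate logistic fit (perfect separation)",
          class = "tempbias_estimation_failure")
  }
  xm <- cbind(1, x)
  w <- mu * (1 - mu)
  xtw <- crossprod(xm, xm * w)
  se <- sqrt(diag(solve(xtw)))
  list(coefficient = unname(coef(fit)[2L]), se = unname(se[2L]),
       intercept = unname(coef(fit)[1L]))
}
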