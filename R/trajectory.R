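#' Log-normal law parameters
#'
#' Light container for a log-normal biomarker law: `mu` is the log-scale
#' location (so the median is `exp(mu)`) and `sigma` the log-scale SD.
#'
#' @param mu Log-scale location.
#' @param sigma Log-scale SD, positive.
#' @return An object of class `lognormal_params`.
#' @examples
#' lognormal_params(log(60), 1)
#' @export
lognormal_params <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    abort("`mu` must be a single finite number.", class = "tempbias_invalid_parameter")
  }
  check_positive_scalar(sigma, "sigma")
  structure(list(mu = mu, sigma = sigma), class = "lognormal_params")
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf("<lognormal_params> mu = %.4f, sigma = %.4f (median %.2f)\n",
              x$mu, x$sigma, exp(x$mu)))
  invisible(x)
}

#' Fit a log-normal law to a centile table
#'
#' Recovers `(mu, sigma)` by least squares of `log(value)` against
#' `mu + sigma * qnorm(percentile)`. On exact log-normal quantiles the fit
#' is exact; on perturbed tables it is the usual quantile regression on the
#' probit scale.
#'
#' @param table A centile table (columns `percentile`, `value`, optionally
#'   `arm`), e.g. one arm of [make_standin_centiles()].
#' @param arm If `table` carries an `arm` column with several arms, which
#'   one to fit.
#' @return A [lognormal_params()] object.
#' @examples
#' ct <- make_standin_centiles(generator_params())
#' fit_lognormal_from_centiles(ct, arm = "case")
#' @export
fit_lognormal_from_centiles <- function(table, arm = NULL) {
  if ("arm" %in% names(table)) {
    arms <- unique(table$arm)
    if (is.null(arm)) {
      if (length(arms) > 1) {
        abort("table holds several arms; pass `arm` to pick one.",
              class = "tempbias_invalid_input")
      }
    } else {
      table <- table[table$arm == arm, , drop = FALSE]
    }
  }
  table <- table[order(table$percentile), , drop = FALSE]
  validate_centile_table(table)
  z <- qnorm(table$percentile)
  fit <- stats::lm.fit(cbind(1, z), log(table$value))
  sigma <- unname(fit$coefficients[2L])
  if (!is.finite(sigma) || sigma <= 0) {
    abort("fitted sigma is not positive; the table is not log-normal-like.",
          class = "tempbias_invalid_input")
  }
  lognormal_params(unname(fit$coefficients[1L]), sigma)
}

#' Control-to-case trajectory specification
#'
#' Describes one case's path from a healthy-era start value to the value
#' observed at the case event, on normalized time t in \[0, 1\]. Four
#' functional families are supported:
#'
#' * `linear`: `start + (end - start) * t`
#' * `logarithmic`: `start + (end - start) * log(1 + k t) / log(1 + k)`
#'   (curvature `k > 0`, default 99) — front-loaded rise.
#' * `logistic`: a standard logistic in t rescaled so the endpoints are hit
#'   exactly (steepness `k > 0`, default 10).
#' * `heaviside`: `start` for `t < p`, `end` for `t >= p` (impulse fraction
#'   `p` in (0, 1)); right-continuous, i.e. the jump completes at `t = p`.
#'
#' All families return exactly `start` at `t = 0` and `end` at `t = 1`,
#' and are non-decreasing in t when `start <= end`.
#'
#' @param start,end Positive biomarker values (vectors recycle).
#' @param shape One of `"linear"`, `"logistic"`, `"logarithmic"`,
#'   `"heaviside"`.
#' @param shape_param Steepness/curvature `k`, or the impulse fraction `p`
#'   for `heaviside`. `NULL` picks the family default (logistic 10,
#'   logarithmic 99, heaviside 0.1; linear has none).
#' @return A tibble of class `trajectory_spec` with columns `start`, `end`,
#'   `shape`, `shape_param`.
#' @examples
#' trajectory_spec(10, 20, "linear")
#' trajectory_spec(10, 20, "heaviside", 0.1)
#' @export
trajectory_spec <- function(start, end,
                            shape = c("linear", "logistic", "logarithmic",
                                      "heaviside"),
                            shape_param = NULL) {
  shape <- match.arg(shape)
  if (any(start <= 0) || any(end <= 0)) {
    abort("`start` and `end` must be strictly positive.",
          class = "tempbias_invalid_input")
  }
  shape_param <- default_shape_param(shape, shape_param)
  out <- tibble::tibble(start = start, end = end, shape = shape,
                        shape_param = shape_param)
  class(out) <- c("trajectory_spec", class(out))
  out
}

default_shape_param <- function(shape, shape_param) {
  if (is.null(shape_param)) {
    shape_param <- switch(shape,
                          linear = NA_real_,
                          logistic = 10,
                          logarithmic = 99,
                          heaviside = 0.1)
  }
  if (shape == "heaviside") {
    if (any(shape_param <= 0 | shape_param >= 1)) {
      abort("heaviside impulse fraction must lie in (0, 1).",
            class = "tempbias_invalid_parameter")
    }
  } else if (shape %in% c("logistic", "logarithmic")) {
    if (any(!is.finite(shape_param) | shape_param <= 0)) {
      abort(sprintf("`shape_param` (k) must be positive for %s trajectories.",
                    shape),
            class = "tempbias_invalid_parameter")
    }
  }
  shape_param
}

# Vectorized core over aligned start/end/param vectors and t.
trajectory_value_core <- function(start, end, shape, shape_param, t) {
  delta <- end - start
  switch(shape,
    linear = start + delta * t,
    logarithmic = start + delta * log1p(shape_param * t) / log1p(shape_param),
    logistic = {
      k <- shape_param
      lo <- plogis(-k / 2)
      hi <- plogis(k / 2)
      start + delta * (plogis(k * (t - 0.5)) - lo) / (hi - lo)
    },
    heaviside = ifelse(t < shape_param, start, end),
    abort(sprintf("unknown trajectory shape '%s'", shape),
          class = "tempbias_invalid_parameter")
  )
}

#' Evaluate a trajectory at normalized times
#'
#' @param spec A [trajectory_spec()] (its rows recycle against `t`).
#' @param t Numeric vector of normalized times in \[0, 1\].
#' @return Biomarker values, the longer of `nrow(spec)` and `length(t)`.
#' @examples
#' trajectory_value(trajectory_spec(10, 20, "linear"), c(0, 0.5, 1))
#' @export
trajectory_value <- function(spec, t) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (any(t < 0 | t > 1)) {
    abort("`t` must lie in [0, 1].", class = "tempbias_invalid_input")
  }
  shape <- unique(spec$shape)
  if (length(shape) != 1L) {
    abort("a trajectory_spec evaluated at once must share one shape.",
          class = "tempbias_invalid_input")
  }
  n <- max(nrow(spec), length(t))
  start <- rep_len(spec$start, n)
  end <- rep_len(spec$end, n)
  sp <- rep_len(spec$shape_param, n)
  t <- rep_len(t, n)
  trajectory_value_core(start, end, shape, sp, t)
}

#' Sample observations uniformly in time along trajectories
#'
#' Draws `t ~ Uniform(0, 1)` independently per trajectory row and returns
#' the trajectory value there — the prospective sampling scheme under which
#' a case is equally likely to be observed anywhere between its healthy
#' start and its event.
#'
#' @param spec A [trajectory_spec()].
#' @param n Number of draws per spec row when `spec` has a single row;
#'   ignored (one draw per row) otherwise.
#' @param seed Optional seed.
#' @return Numeric vector of sampled biomarker values.
#' @examples
#' sample_case_observation(trajectory_spec(10, 20, "linear"), n = 5, seed = 1)
#' @export
sample_case_observation <- function(spec, n = NULL, seed = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"))
  seed_rng(seed)
  m <- if (nrow(spec) == 1L && !is.null(n)) n else nrow(spec)
  trajectory_value(spec, runif(m))
}

#' Impute a healthy-era start value for each case observation
#'
#' Three schemes for assigning each case a start value representing its
#' biomarker level back when it was indistinguishable from a control:
#'
#' * `weighted_sampling`: a draw from the control law truncated to
#'   `(0, case_value)`, implemented by inverse CDF on
#'   `U(0, F_control(case_value))` (same law as rejection sampling from the
#'   control distribution conditional on falling below the case value).
#' * `percentile_matching`: the control quantile at the case law's
#'   percentile of the case value, so a case at its distribution's median
#'   starts at the control median.
#' * `percent_shift`: `(1 - shift_fraction) * case_value` (default a 15%
#'   shift, mirroring a 15% control-vs-case median gap).
#'
#' @param case_value Positive case biomarker value(s) at the event.
#' @param control,case [lognormal_params()] for the two arms (the case law
#'   is only used by `percentile_matching`).
#' @param method One of `"weighted_sampling"`, `"percentile_matching"`,
#'   `"percent_shift"`.
#' @param shift_fraction Fractional shift for `percent_shift`, in (0, 1).
#' @param seed Optional seed (only `weighted_sampling` consumes randomness).
#' @return Imputed start value(s), same length as `case_value`.
#' @examples
#' ctrl <- lognormal_params(log(51), 1)
#' cs <- lognormal_params(log(60), 1)
#' impute_start_value(100, ctrl, cs, "percent_shift")
#' impute_start_value(60, ctrl, cs, "percentile_matching")
#' @export
impute_start_value <- function(case_value, control, case,
                               method = c("weighted_sampling",
                                          "percentile_matching",
                                          "percent_shift"),
                               shift_fraction = 0.15, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(control, "lognormal_params"))
  if (any(!is.finite(case_value) | case_value <= 0)) {
    abort("`case_value` must be strictly positive.",
          class = "tempbias_invalid_input")
  }
  seed_rng(seed)
  switch(method,
    percent_shift = {
      check_fraction(shift_fraction, "shift_fraction")
      (1 - shift_fraction) * case_value
    },
    percentile_matching = {
      stopifnot(inherits(case, "lognormal_params"))
      stats::qlnorm(stats::plnorm(case_value, case$mu, case$sigma),
                    control$mu, control$sigma)
    },
    weighted_sampling = {
      upper <- stats::plnorm(case_value, control$mu, control$sigma)
      stats::qlnorm(runif(length(case_value)) * upper,
                    control$mu, control$sigma)
    }
  )
}
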