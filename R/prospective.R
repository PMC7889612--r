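#' Temporally biased baseline association
#'
#' Draws `n_per_arm` biomarker values per arm at their observed laws — for
#' cases, the end-of-trajectory (event-time) distribution — and fits a
#' logistic regression of case status on the value. This is the effect a
#' case-control study reports when every case is sampled exactly at its
#' event.
#'
#' @param case,control [lognormal_params()] of the two arms.
#' @param n_per_arm Draws per arm (at least 100).
#' @param seed Optional seed.
#' @return A `tb_effect` object: list with `coefficient` (log-odds per
#'   biomarker unit), `se`, `n_case`, `n_control`, `seed`.
#' @examples
#' laws <- standin_laws(generator_params())
#' baseline_effect(laws$case, laws$control, n_per_arm = 1000, seed = 1)
#' @export
baseline_effect <- function(case, control, n_per_arm = 150000L, seed = NULL) {
  stopifnot(inherits(case, "lognormal_params"),
            inherits(control, "lognormal_params"))
  if (n_per_arm < 100) {
    abort("`n_per_arm` must be at least 100.", class = "tempbias_invalid_parameter")
  }
  seed_rng(seed)
  x_case <- stats::rlnorm(n_per_arm, case$mu, case$sigma)
  x_ctrl <- stats::rlnorm(n_per_arm, control$mu, control$sigma)
  fit <- fit_logit(c(x_case, x_ctrl), rep(c(1, 0), each = n_per_arm))
  new_tb_effect(fit, n_per_arm, n_per_arm, seed, design = "baseline")
}

#' Prospective (uniform-in-time) association under an imputed trajectory
#'
#' Re-estimates the case-control association as if cases had been observed
#' at a uniformly random time along their control-to-case trajectory
#' rather than at the event. Per case draw: the event-time value is drawn
#' from the case law, a healthy-era start is imputed (see
#' [impute_start_value()]), a trajectory of the requested shape connects
#' the two, and the observation is replaced by the trajectory value at
#' `t ~ U(0, 1)`. Controls are drawn as in [baseline_effect()] and the
#' same logistic model is fit.
#'
#' @inheritParams baseline_effect
#' @param shape,shape_param Trajectory family, see [trajectory_spec()].
#' @param method,shift_fraction Start-value imputation, see
#'   [impute_start_value()].
#' @return A `tb_effect` object.
#' @examples
#' laws <- standin_laws(generator_params())
#' prospective_trial(laws$case, laws$control, shape = "heaviside",
#'                   shape_param = 0.1, method = "percentile_matching",
#'                   n_per_arm = 1000, seed = 1)
#' @export
prospective_trial <- function(case, control,
                              shape = c("linear", "logistic", "logarithmic",
                                        "heaviside"),
                              method = c("weighted_sampling",
                                         "percentile_matching",
                                         "percent_shift"),
                              n_per_arm = 150000L, seed = NULL,
                              shape_param = NULL, shift_fraction = 0.15) {
  shape <- match.arg(shape)
  method <- match.arg(method)
  stopifnot(inherits(case, "lognormal_params"),
            inherits(control, "lognormal_params"))
  if (n_per_arm < 100) {
    abort("`n_per_arm` must be at least 100.", class = "tempbias_invalid_parameter")
  }
  seed_rng(seed)
  shape_param <- default_shape_param(shape, shape_param)
  end <- stats::rlnorm(n_per_arm, case$mu, case$sigma)
  start <- impute_start_value(end, control, case, method,
                              shift_fraction = shift_fraction)
  t <- runif(n_per_arm)
  obs <- trajectory_value_core(start, end, shape, shape_param, t)
  x_ctrl <- stats::rlnorm(n_per_arm, control$mu, control$sigma)
  fit <- fit_logit(c(obs, x_ctrl), rep(c(1, 0), each = n_per_arm))
  new_tb_effect(fit, n_per_arm, n_per_arm, seed,
                design = "prospective", shape = shape,
                shape_param = shape_param, method = method)
}

new_tb_effect <- function(fit, n_case, n_control, seed, design,
                          shape = NA_character_, shape_param = NA_real_,
                          method = NA_character_) {
  structure(
    list(coefficient = fit$coefficient, se = fit$se,
         n_case = n_case, n_control = n_control,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         design = design, shape = shape, shape_param = shape_param,
         method = method),
    class = "tb_effect"
  )
}

#' @export
print.tb_effect <- function(x, ...) {
  cat(sprintf("<tb_effect> %s: coefficient %.5g (se %.3g), n = %d + %d\n",
              x$design, x$coefficient, x$se, x$n_case, x$n_control))
  if (!is.na(x$method)) {
    cat(sprintf("  imputation %s, trajectory %s (param %s)\n",
                x$method, x$shape, format(x$shape_param)))
  }
  invisible(x)
}

#' Helper: stand-in biomarker laws straight from generator parameters
#'
#' Convenience wrapper producing the case/control [lognormal_params()]
#' implied by a [generator_params()] configuration (the same pair that
#' [make_standin_centiles()] tabulates).
#'
#' @param params A [generator_params()] list.
#' @return List with elements `case` and `control`.
#' @examples
#' standin_laws(generator_params())
#' @export
standin_laws <- function(params = generator_params()) {
  stopifnot(inherits(params, "tempbias_params"))
  list(case = lognormal_params(log(params$median_case), params$sigma_log),
       control = lognormal_params(log(params$median_case * params$median_ratio),
                                  params$sigma_log))
}

# Default (method x shape) grid mirroring the attenuation table layout:
# three imputation methods crossed with linear, logistic, logarithmic and
# three Heaviside impulse fractions.
default_effect_grid <- function() {
  shapes <- tibble::tibble(
    shape = c("linear", "logistic", "logarithmic",
              "heaviside", "heaviside", "heaviside"),
    shape_param = c(NA, 10, 99, 0.1, 0.01, 0.001)
  )
  methods <- c("weighted_sampling", "percentile_matching", "percent_shift")
  tidyr::crossing(method = methods, shapes)
}

#' Relative prospective effect sizes over a method x shape grid
#'
#' The attenuation table pipeline: for every combination of start-value
#' imputation method and trajectory shape, runs `n_reps` independent
#' repetitions. Each repetition draws a fresh cohort, fits the temporally
#' biased baseline ([baseline_effect()] on the same case end values), fits
#' the prospective model with the case observations replaced by
#' uniform-time trajectory samples, and records the coefficient ratio
#' (prospective / baseline). A ratio of 1 means no attenuation; ratios
#' below 1 quantify how much of the reported association is an artifact of
#' sampling cases at their event.
#'
#' @param case,control [lognormal_params()] of the two arms, e.g. from
#'   [fit_lognormal_from_centiles()] on a centile table.
#' @param grid Tibble with columns `method`, `shape`, `shape_param`; the
#'   default crosses the three imputation methods with linear, logistic
#'   (k = 10), logarithmic (k = 99) and Heaviside impulse fractions
#'   0.1 / 0.01 / 0.001.
#' @param n_reps Repetitions per cell (default 100).
#' @param n_per_arm Draws per arm per repetition.
#' @param shift_fraction Shift used by the `percent_shift` method.
#' @param seed Seed for the whole summary (fixes every repetition).
#' @return A tibble of class `tb_releffect`: one row per grid cell with
#'   `ratio_mean`, empirical 95% interval `ci_lo`/`ci_hi` (2.5th/97.5th
#'   percentile across repetitions), `n_reps`, `n_failed`.
#' @examples
#' laws <- standin_laws(generator_params())
#' relative_effect_summary(laws$case, laws$control,
#'                         grid = tibble::tibble(method = "percentile_matching",
#'                                               shape = "heaviside",
#'                                               shape_param = 0.1),
#'                         n_reps = 3, n_per_arm = 1000, seed = 1)
#' @export
relative_effect_summary <- function(case, control,
                                    grid = default_effect_grid(),
                                    n_reps = 100L, n_per_arm = 150000L,
                                    shift_fraction = 0.15, seed = NULL) {
  stopifnot(inherits(case, "lognormal_params"),
            inherits(control, "lognormal_params"))
  if (n_reps < 2) {
    abort("`n_reps` must be at least 2.", class = "tempbias_invalid_parameter")
  }
  if (!all(c("method", "shape") %in% names(grid))) {
    abort("`grid` needs `method` and `shape` columns.",
          class = "tempbias_invalid_input")
  }
  if (!"shape_param" %in% names(grid)) grid$shape_param <- NA_real_
  seed_rng(seed)

  cells <- purrr::pmap(grid, function(method, shape, shape_param, ...) {
    sp <- default_shape_param(shape,
                              if (is.na(shape_param)) NULL else shape_param)
    ratios <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      ratios[r] <- tryCatch({
        end <- stats::rlnorm(n_per_arm, case$mu, case$sigma)
        x_ctrl <- stats::rlnorm(n_per_arm, control$mu, control$sigma)
        y <- rep(c(1, 0), each = n_per_arm)
        b0 <- fit_logit(c(end, x_ctrl), y)$coefficient
        start <- impute_start_value(end, control, case, method,
                                    shift_fraction = shift_fraction)
        obs <- trajectory_value_core(start, end, shape, sp, runif(n_per_arm))
        b1 <- fit_logit(c(obs, x_ctrl), y)$coefficient
        b1 / b0
      }, tempbias_estimation_failure = function(e) NA_real_)
    }
    ok <- ratios[!is.na(ratios)]
    n_failed <- sum(is.na(ratios))
    if (n_failed > 0.1 * n_reps) {
      abort(sprintf("more than 10%% of repetitions failed for %s x %s.",
                    method, shape),
            class = "tempbias_estimation_failure")
    }
    tibble::tibble(
      method = method, shape = shape, shape_param = sp,
      ratio_mean = mean(ok),
      ci_lo = unname(quantile(ok, 0.025)),
      ci_hi = unname(quantile(ok, 0.975)),
      n_reps = length(ok), n_failed = n_failed
    )
  })
  out <- dplyr::bind_rows(cells)
  attr(out, "n_per_arm") <- n_per_arm
  attr(out, "seed") <- seed
  class(out) <- c("tb_releffect", class(out))
  out
}
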