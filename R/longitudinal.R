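#' Synthetic longitudinal yearly-exposure cohort
#'
#' Generates a survey-style cohort: each subject contributes one exposure
#' value (e.g. servings/day of a food item) per survey year from a random
#' entry year until their first event year (cases) or the end of follow-up
#' (controls). Exposures follow subject-mean + AR(1) noise, truncated at
#' zero. The event hazard in year t is logit-linear in that same year's
#' exposure only — the association is wholly concentrated in the most
#' recent year, which is the ground truth the lookback sweep probes.
#'
#' @param params A [generator_params()] list.
#' @param seed Seed; defaults to `params$seed`.
#' @return A tibble of class `longitudinal_cohort`, one row per
#'   subject-year: `subject_id`, `sex`, `birth_year`, `entry_year`,
#'   `year`, `exposure`, `event_year` (`NA` for event-free subjects).
#' @examples
#' lc <- gen_longitudinal_cohort(generator_params(n_subjects = 200))
#' dplyr::n_distinct(lc$subject_id)
#' @export
gen_longitudinal_cohort <- function(params = generator_params(),
                                    seed = params$seed) {
  stopifnot(inherits(params, "tempbias_params"))
  seed_rng(seed)
  n <- params$n_subjects
  yrs <- params$years
  ny <- length(yrs)
  if (ny < 3) {
    abort("`years` must span at least 3 survey years.",
          class = "tempbias_invalid_parameter")
  }

  sex <- sample(c("F", "M"), n, replace = TRUE)
  birth_year <- sample_vec(seq(min(yrs) - 60L, min(yrs) - 35L), n)
  # entry early enough that every subject can hold >= 2 surveys
  entry_year <- sample_vec(yrs[seq_len(max(1L, ny - 5L))], n)

  subj_mean <- pmax(rnorm(n, params$exposure_mean, params$subject_sd), 0)
  rho <- params$ar1_rho
  eps <- matrix(NA_real_, n, ny)
  sd_stat <- params$innovation_sd / sqrt(1 - rho^2)
  eps[, 1] <- rnorm(n, 0, sd_stat)
  for (j in 2:ny) {
    eps[, j] <- rho * eps[, j - 1] + rnorm(n, 0, params$innovation_sd)
  }
  expo <- pmax(subj_mean + eps, 0)

  # first event: hazard in year t depends only on exposure in year t;
  # events possible from the year after entry so cases retain >= 2 surveys
  p_ev <- plogis(params$hazard_intercept + params$effect_coef * expo)
  at_risk <- outer(entry_year, yrs, function(e, y) y >= e + 1L)
  hit <- (matrix(runif(n * ny), n, ny) < p_ev) & at_risk
  first <- apply(hit, 1L, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  event_year <- ifelse(is.na(first), NA_integer_, yrs[first])

  # long format: rows from entry through event year (cases) / end (controls)
  last_year <- ifelse(is.na(event_year), max(yrs), event_year)
  keep <- outer(entry_year, yrs, `<=`) & outer(last_year, yrs, `>=`)
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble::tibble(
    subject_id = sprintf("S%06d", idx[, 1]),
    sex = sex[idx[, 1]],
    birth_year = birth_year[idx[, 1]],
    entry_year = entry_year[idx[, 1]],
    year = yrs[idx[, 2]],
    exposure = expo[idx],
    event_year = event_year[idx[, 1]]
  )
  out <- dplyr::arrange(out, .data$subject_id, .data$year)
  attr(out, "params") <- params
  class(out) <- c("longitudinal_cohort", class(out))
  out
}

#' Synthetic repeated biomarker measurements
#'
#' Generates subjects with a latent true biomarker level (log-normal) and
#' `n_tests` noisy test values each: true level plus zero-mean normal
#' noise truncated at zero (the biomarker cannot be negative). The latent
#' noise SD is inflated by `1 / c4(n_tests)` so that the expected
#' per-subject sample SD (n-1 denominator) matches `rm_noise_sd`; the
#' log-scale location is chosen so the expected grand mean of tests
#' matches `rm_target_mean`. Outcome status is drawn logit-linearly in the
#' true level.
#'
#' @param params A [generator_params()] list.
#' @param seed Seed; defaults to `params$seed`.
#' @return A tibble of class `repeated_measures_cohort`, one row per test:
#'   `subject_id`, `true_level`, `test`, `value`, `mi_status`.
#' @examples
#' rm <- gen_repeated_measures(generator_params(n_rm_subjects = 100))
#' nrow(rm)
#' @export
gen_repeated_measures <- function(params = generator_params(),
                                  seed = params$seed) {
  stopifnot(inherits(params, "tempbias_params"))
  seed_rng(seed)
  n <- params$n_rm_subjects
  k <- params$n_tests
  c4 <- sqrt(2 / (k - 1)) * gamma(k / 2) / gamma((k - 1) / 2)
  sd_latent <- params$rm_noise_sd / c4
  # Truncating the noise at zero inflates the mean of observed tests by
  # E[sd * phi(x/sd) / Phi(x/sd)] over the true-level law; place the
  # latent log-normal so the expected observed grand mean hits the target.
  meanlog <- log(params$rm_target_mean) - params$rm_sigma_log^2 / 2
  if (sd_latent > 0) {
    qq <- stats::qlnorm(seq(0.0005, 0.9995, length.out = 2000),
                        meanlog, params$rm_sigma_log)
    bias <- mean(sd_latent * stats::dnorm(qq / sd_latent) /
                   pnorm(qq / sd_latent))
    meanlog <- log(max(params$rm_target_mean - bias,
                       params$rm_target_mean / 2)) -
      params$rm_sigma_log^2 / 2
  }
  true <- stats::rlnorm(n, meanlog, params$rm_sigma_log)
  intercept <- qlogis(params$mi_prevalence) -
    params$mi_coef * params$rm_target_mean
  mi <- rbinom(n, 1, plogis(intercept + params$mi_coef * true))
  values <- if (sd_latent > 0) {
    rnorm_pos(n * k, rep(true, each = k), sd_latent)
  } else {
    rep(true, each = k)
  }
  out <- tibble::tibble(
    subject_id = rep(sprintf("M%06d", seq_len(n)), each = k),
    true_level = rep(true, each = k),
    test = rep(seq_len(k), n),
    value = values,
    mi_status = rep(mi, each = k)
  )
  attr(out, "params") <- params
  class(out) <- c("repeated_measures_cohort", class(out))
  out
}
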