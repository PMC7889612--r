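#' Simulation parameters for the synthetic cohort generators
#'
#' Bundles every knob of the four synthetic-data generators into one
#' validated list. Defaults encode the study conditions the package
#' simulates: a log-normal biomarker whose control-arm median sits 15%
#' below the case-arm median, a claims stream in which case-discriminative
#' codes appear only during the nine months of gestation preceding a
#' delivery (emission rate ramping up toward the event), yearly exposures
#' whose association with the event is confined to the most recent year,
#' and repeated biomarker tests calibrated so the observed grand mean is
#' about 49.4 mg/dl with a mean within-subject standard deviation of about
#' 12.2 mg/dl.
#'
#' @param seed Default integer seed used by generators when no explicit
#'   seed is passed to them.
#' @param median_case Case-arm biomarker median, mg/dl.
#' @param median_ratio Control median divided by case median, in (0, 1).
#' @param sigma_log Shared log-scale standard deviation of both biomarker
#'   arms.
#' @param percentiles Percentile grid used for stand-in centile tables.
#' @param n_cases,n_controls Claims cohort arm sizes (after matching).
#' @param control_pool_factor The generator emits
#'   `control_pool_factor * n_controls` candidate controls, emulating
#'   selection of matched controls from a large claims database; exact
#'   matching then keeps one control per case.
#' @param gestation_months Length of the gestation span, in months
#'   (at most 11 so the span fits a calendar year).
#' @param gestational_rate Peak monthly Poisson rate of gestational-class
#'   codes, reached at the delivery month.
#' @param gestational_rate_min Monthly gestational rate at conception; the
#'   rate ramps linearly from this floor up to `gestational_rate`.
#' @param background_rate Monthly Poisson rate of background codes, emitted
#'   homogeneously all year for every patient.
#' @param n_background_codes Size of the background code vocabulary.
#' @param codes_per_stage Number of gestational codes tied to each
#'   gestation stage.
#' @param stage_band An event at gestation stage s draws its code among
#'   the codes of stages within `stage_band` of s; small bands make each
#'   gestation month's code signature distinctive.
#' @param age_range Two integers, inclusive age range of claims patients.
#' @param n_regions Number of region codes used for matching.
#' @param n_subjects Longitudinal cohort size.
#' @param years Survey years covered by the longitudinal cohort.
#' @param exposure_mean Population mean yearly consumption (servings/day).
#' @param subject_sd SD of subject-level mean consumption.
#' @param innovation_sd SD of the AR(1) innovations around the subject mean.
#' @param ar1_rho AR(1) autocorrelation of yearly exposure noise, in [0, 1).
#' @param effect_coef Log-odds of the event per unit of current-year
#'   exposure; negative for a protective exposure. The event hazard depends
#'   only on the most recent year's exposure.
#' @param hazard_intercept Log-odds of the event in a year at zero exposure.
#' @param n_rm_subjects Repeated-measures cohort size.
#' @param n_tests Number of biomarker tests per subject (at least 2).
#' @param rm_target_mean Target observed grand mean of tests, mg/dl.
#' @param rm_noise_sd Target observed mean within-subject sample SD of
#'   tests, mg/dl. The latent noise SD is inflated by the reciprocal of the
#'   c4 small-sample constant so that the expected per-subject sample SD
#'   (computed with the n-1 denominator) matches this value.
#' @param rm_sigma_log Log-scale SD of the latent true biomarker levels.
#' @param mi_coef Log-odds of the outcome per mg/dl of true biomarker level.
#' @param mi_prevalence Target marginal outcome prevalence in the
#'   repeated-measures cohort.
#'
#' @return A list of class `tempbias_params`.
#' @examples
#' p <- generator_params(n_cases = 100, n_controls = 100)
#' p$median_ratio
#' @export
generator_params <- function(seed = 1L,
                             # biomarker laws
                             median_case = 60,
                             median_ratio = 0.85,
                             sigma_log = 0.25,
                             percentiles = c(0.025, 0.05, 0.1, 0.25, 0.5,
                                             0.75, 0.9, 0.95, 0.975),
                             # claims cohort
                             n_cases = 3000L,
                             n_controls = 3000L,
                             control_pool_factor = 3,
                             gestation_months = 9L,
                             gestational_rate = 3,
                             gestational_rate_min = 0.1,
                             background_rate = 2,
                             n_background_codes = 30L,
                             codes_per_stage = 2L,
                             stage_band = 1L,
                             age_range = c(18L, 45L),
                             n_regions = 8L,
                             # longitudinal cohort
                             n_subjects = 30000L,
                             years = 1994:2010,
                             exposure_mean = 3,
                             subject_sd = 0.1,
                             innovation_sd = 1,
                             ar1_rho = 0,
                             effect_coef = -0.28,
                             hazard_intercept = -4.3,
                             # repeated measures
                             n_rm_subjects = 5000L,
                             n_tests = 4L,
                             rm_target_mean = 49.4,
                             rm_noise_sd = 12.2,
                             rm_sigma_log = 0.6,
                             mi_coef = 0.02,
                             mi_prevalence = 0.3) {
  check_positive_scalar(median_case, "median_case")
  check_fraction(median_ratio, "median_ratio")
  check_positive_scalar(sigma_log, "sigma_log")
  if (!is.numeric(percentiles) || length(percentiles) < 1 ||
      any(percentiles <= 0 | percentiles >= 1) ||
      is.unsorted(percentiles, strictly = TRUE)) {
    abort("`percentiles` must be strictly increasing fractions in (0, 1).",
          class = "tempbias_invalid_parameter")
  }
  if (gestation_months > 11) {
    abort("`gestation_months` must be at most 11 (the span must fit the data year).",
          class = "tempbias_invalid_parameter")
  }
  if (gestation_months < 1) {
    abort("`gestation_months` must be at least 1.",
          class = "tempbias_invalid_parameter")
  }
  for (nm in c("gestational_rate", "gestational_rate_min", "background_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("`%s` must be a non-negative rate.", nm),
            class = "tempbias_invalid_parameter")
    }
  }
  if (gestational_rate_min > gestational_rate) {
    abort("`gestational_rate_min` must not exceed `gestational_rate` (the ramp is non-decreasing).",
          class = "tempbias_invalid_parameter")
  }
  if (!(is.numeric(ar1_rho) && length(ar1_rho) == 1L && ar1_rho >= 0 && ar1_rho < 1)) {
    abort("`ar1_rho` must lie in [0, 1).", class = "tempbias_invalid_parameter")
  }
  if (!is.finite(effect_coef)) {
    abort("`effect_coef` must be finite.", class = "tempbias_invalid_parameter")
  }
  if (n_tests < 2) {
    abort("`n_tests` must be at least 2.", class = "tempbias_invalid_parameter")
  }
  if (!is.numeric(rm_noise_sd) || rm_noise_sd < 0) {
    abort("`rm_noise_sd` must be non-negative.", class = "tempbias_invalid_parameter")
  }
  check_positive_scalar(rm_target_mean, "rm_target_mean")
  check_positive_scalar(rm_sigma_log, "rm_sigma_log")
  check_fraction(mi_prevalence, "mi_prevalence")

  structure(
    list(
      seed = as.integer(seed),
      median_case = median_case, median_ratio = median_ratio,
      sigma_log = sigma_log, percentiles = percentiles,
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      control_pool_factor = control_pool_factor,
      gestation_months = as.integer(gestation_months),
      gestational_rate = gestational_rate,
      gestational_rate_min = gestational_rate_min,
      background_rate = background_rate,
      n_background_codes = as.integer(n_background_codes),
      codes_per_stage = as.integer(codes_per_stage),
      stage_band = as.integer(stage_band),
      age_range = as.integer(age_range), n_regions = as.integer(n_regions),
      n_subjects = as.integer(n_subjects), years = as.integer(years),
      exposure_mean = exposure_mean, subject_sd = subject_sd,
      innovation_sd = innovation_sd, ar1_rho = ar1_rho,
      effect_coef = effect_coef, hazard_intercept = hazard_intercept,
      n_rm_subjects = as.integer(n_rm_subjects), n_tests = as.integer(n_tests),
      rm_target_mean = rm_target_mean, rm_noise_sd = rm_noise_sd,
      rm_sigma_log = rm_sigma_log, mi_coef = mi_coef,
      mi_prevalence = mi_prevalence
    ),
    class = "tempbias_params"
  )
}

#' @export
print.tempbias_params <- function(x, ...) {
  cat("<tempbias_params>\n")
  cat(sprintf("  biomarker: median_case %.1f, median_ratio %.2f, sigma_log %.2f\n",
              x$median_case, x$median_ratio, x$sigma_log))
  cat(sprintf("  claims: %d cases / %d controls, gestation %d mo\n",
              x$n_cases, x$n_controls, x$gestation_months))
  cat(sprintf("  longitudinal: %d subjects, years %d-%d, effect %.2f\n",
              x$n_subjects, min(x$years), max(x$years), x$effect_coef))
  cat(sprintf("  repeated: %d subjects x %d tests, target mean %.1f / wsd %.1f\n",
              x$n_rm_subjects, x$n_tests, x$rm_target_mean, x$rm_noise_sd))
  invisible(x)
}
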