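#' Reduce a subject's repeated measurements to one exposure value
#'
#' @param measurements Numeric vector of test values (at least 1).
#' @param scheme `"max"`, `"min"`, `"mean"` or `"random_single"` (one
#'   measurement drawn uniformly).
#' @param seed Optional seed (`random_single` only).
#' @return A single exposure value.
#' @examples
#' select_exposure(c(40, 60, 50), "max")
#' select_exposure(c(40, 60, 50), "mean")
#' @export
select_exposure <- function(measurements,
                            scheme = c("max", "min", "mean", "random_single"),
                            seed = NULL) {
  scheme <- match.arg(scheme)
  if (length(measurements) < 1) {
    abort("`measurements` must be non-empty.", class = "tempbias_invalid_input")
  }
  seed_rng(seed)
  switch(scheme,
         max = max(measurements),
         min = min(measurements),
         mean = mean(measurements),
         random_single = measurements[sample.int(length(measurements), 1L)])
}

#' Intra-individual variation of repeated tests
#'
#' @param cohort A [gen_repeated_measures()] tibble (needs `subject_id`
#'   and `value`); every subject must have at least 2 tests.
#' @return A one-row tibble: `mean_within_subject_sd` (mean over subjects
#'   of the per-subject sample SD, n-1 denominator) and `grand_mean` (mean
#'   over all tests).
#' @examples
#' rm <- tibble::tibble(subject_id = rep(c("a", "b"), each = 2),
#'                      value = c(1, 3, 2, 4))
#' intra_individual_variation(rm)
#' @export
intra_individual_variation <- function(cohort) {
  per <- dplyr::summarise(dplyr::group_by(cohort, .data$subject_id),
                          n = dplyr::n(), s = sd(.data$value),
                          .groups = "drop")
  if (any(per$n < 2)) {
    abort("every subject needs at least 2 measurements.",
          class = "tempbias_invalid_input")
  }
  tibble::tibble(mean_within_subject_sd = mean(per$s),
                 grand_mean = mean(cohort$value))
}

#' Measurement-selection effect on the biomarker-outcome association
#'
#' Quantifies how the choice of which repeated measurement represents a
#' subject moves the fitted association. The reference exposure is a
#' measurement drawn uniformly per subject (`random_single`), applied to
#' every subject. Each biased scheme replaces the CASE subjects' exposure
#' by the scheme's reduction of their tests (largest, smallest, mean)
#' while controls keep their random timepoint — biased selection acts on
#' the case measurements, which is how preferential sampling of case
#' values arises in practice. A logistic regression of outcome status on
#' the exposure is fit per scheme and each coefficient is reported as a
#' ratio to the `random_single` coefficient.
#'
#' @param cohort A [gen_repeated_measures()] tibble.
#' @param schemes Character vector of biased schemes to evaluate.
#' @param seed Seed (fixes the random timepoints).
#' @return A tibble of class `tb_selection`, one row per scheme (including
#'   the `random_single` reference): `coefficient`, `se`,
#'   `ratio_vs_random`.
#' @examples
#' \donttest{
#' rm <- gen_repeated_measures(generator_params(n_rm_subjects = 2000))
#' selection_effect_analysis(rm, seed = 1)
#' }
#' @export
selection_effect_analysis <- function(cohort,
                                      schemes = c("min", "max", "mean"),
                                      seed = NULL) {
  seed_rng(seed)
  per <- dplyr::summarise(
    dplyr::group_by(cohort, .data$subject_id),
    mi_status = .data$mi_status[1],
    v_min = min(.data$value), v_max = max(.data$value),
    v_mean = mean(.data$value), n = dplyr::n(),
    .groups = "drop"
  )
  if (length(unique(per$mi_status)) < 2) {
    abort("outcome must have both classes.",
          class = "tempbias_estimation_failure")
  }
  # one uniformly drawn timepoint per subject: the reference exposure
  pick <- stats::ave(seq_len(nrow(cohort)), cohort$subject_id,
                     FUN = function(i) i[sample.int(length(i), 1L)])
  rnd <- cohort$value[unique(pick)]
  names(rnd) <- cohort$subject_id[unique(pick)]
  per$v_random <- unname(rnd[per$subject_id])

  y <- per$mi_status
  fits <- list(random_single = fit_logit(per$v_random, y))
  for (s in schemes) {
    biased <- switch(s, min = per$v_min, max = per$v_max, mean = per$v_mean,
                     abort(sprintf("unknown scheme '%s'", s),
                           class = "tempbias_invalid_parameter"))
    w <- ifelse(y == 1, biased, per$v_random)
    fits[[s]] <- fit_logit(w, y)
  }
  out <- tibble::tibble(
    scheme = names(fits),
    coefficient = unname(vapply(fits, `[[`, numeric(1), "coefficient")),
    se = unname(vapply(fits, `[[`, numeric(1), "se"))
  )
  out$ratio_vs_random <- out$coefficient /
    out$coefficient[out$scheme == "random_single"]
  class(out) <- c("tb_selection", class(out))
  out
}
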