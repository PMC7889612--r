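#' Cumulative exposure over a lookback window
#'
#' Sums each subject's yearly exposure over the `lookback_years` years
#' ending at their baseline year (`baseline_year - lookback_years + 1`
#' through `baseline_year`). Subjects missing any survey year in the span
#' are flagged and excluded from downstream trials, mirroring the
#' consecutive-survey eligibility rule.
#'
#' @param cohort A [gen_longitudinal_cohort()] tibble (or any tibble with
#'   `subject_id`, `year`, `exposure`).
#' @param baselines Tibble with `subject_id` and `baseline_year`.
#' @param lookback_years Window length L, in years (>= 1).
#' @return `baselines` with `cum_exposure` (NA when the span is not fully
#'   covered) and `complete` columns.
#' @examples
#' lc <- tibble::tibble(subject_id = "a", year = 2001:2003,
#'                      exposure = c(2, 3, 4))
#' cumulative_exposure(lc, tibble::tibble(subject_id = "a",
#'                                        baseline_year = 2003), 3)
#' @export
cumulative_exposure <- function(cohort, baselines, lookback_years) {
  if (lookback_years < 1) {
    abort("`lookback_years` must be at least 1.",
          class = "tempbias_invalid_parameter")
  }
  span <- dplyr::inner_join(
    dplyr::select(baselines, "subject_id", "baseline_year"),
    dplyr::select(cohort, "subject_id", "year", "exposure"),
    by = "subject_id", relationship = "many-to-many"
  )
  span <- span[span$year >= span$baseline_year - lookback_years + 1 &
                 span$year <= span$baseline_year, ]
  agg <- dplyr::summarise(dplyr::group_by(span, .data$subject_id,
                                          .data$baseline_year),
                          cum_exposure = sum(.data$exposure),
                          n_years = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(baselines, agg,
                          by = c("subject_id", "baseline_year"))
  out$complete <- !is.na(out$n_years) & out$n_years == lookback_years
  out$cum_exposure[!out$complete] <- NA_real_
  dplyr::select(out, -"n_years")
}

#' Split values at the top quintile
#'
#' Labels 1 every value at or above the 80th-percentile cut (type-7
#' quantile); ties at the cut are all labeled 1, so heavy ties can push
#' the labeled fraction above 20%.
#'
#' @param values Numeric vector, length at least 5.
#' @return Integer 0/1 labels.
#' @examples
#' sum(top_quintile_split(1:100))  # 20
#' @export
top_quintile_split <- function(values) {
  if (length(values) < 5) {
    abort("need at least 5 values for a quintile split.",
          class = "tempbias_invalid_input")
  }
  if (diff(range(values)) == 0) {
    abort("all values identical: quintile split is degenerate.",
          class = "tempbias_degenerate_split")
  }
  cut <- quantile(values, 0.8, names = FALSE)
  as.integer(values >= cut)
}

# Precompute the per-subject lookup structures one sweep reuses across
# trials: subject table + wide exposure matrix.
lb_prepare <- function(cohort) {
  subj <- dplyr::distinct(cohort, .data$subject_id, .data$sex,
                          .data$birth_year, .data$entry_year,
                          .data$event_year)
  yrs <- sort(unique(cohort$year))
  wide <- matrix(NA_real_, nrow(subj), length(yrs),
                 dimnames = list(subj$subject_id, yrs))
  wide[cbind(match(cohort$subject_id, subj$subject_id),
             match(cohort$year, yrs))] <- cohort$exposure
  list(subjects = subj, wide = wide, years = yrs)
}

lb_sum <- function(prep, rows, baseline_year, L) {
  cols <- match(baseline_year, prep$years)
  out <- numeric(length(rows))
  for (l in seq_len(L) - 1L) {
    out <- out + prep$wide[cbind(rows, cols - l)]
  }
  out
}

# One matched case-control trial at lookback L over prepared structures.
lb_trial_core <- function(prep, L) {
  subj <- prep$subjects
  yrs <- prep$years
  is_case <- !is.na(subj$event_year)
  # case eligibility: >= 2 surveys through the event year, and full
  # coverage of the L-year span ending at the event year
  ok_case <- is_case & (subj$event_year - subj$entry_year >= 1) &
    (subj$event_year - L + 1 >= subj$entry_year) &
    (subj$event_year - L + 1 >= min(yrs))
  cases <- subj[ok_case, ]
  n_excluded <- sum(is_case) - nrow(cases)
  cases$baseline_year <- cases$event_year
  cases$age <- cases$baseline_year - cases$birth_year

  ctrl <- subj[!is_case, ]
  # a control of age a (at baseline) has baseline = birth + a, feasible
  # when the L-year span is covered: entry + L - 1 <= baseline <= max year
  ctrl_lo <- ctrl$entry_year + L - 1L - ctrl$birth_year  # min feasible age
  ctrl_hi <- max(yrs) - ctrl$birth_year                  # max feasible age

  used <- rep(FALSE, nrow(ctrl))
  strata <- split(seq_len(nrow(cases)),
                  paste(cases$sex, cases$age, sep = "\r"))
  m_rows <- integer(0); m_ctrl <- integer(0)
  for (s in names(strata)) {
    rows <- strata[[s]]
    sex_s <- cases$sex[rows[1]]
    age_s <- cases$age[rows[1]]
    cand <- which(!used & ctrl$sex == sex_s &
                    ctrl_lo <= age_s & age_s <= ctrl_hi)
    if (length(cand) < length(rows)) {
      abort(sprintf(
        "control pool exhausted in stratum sex=%s age=%d (need %d, have %d).",
        sex_s, age_s, length(rows), length(cand)),
        class = "tempbias_matching_error")
    }
    take <- cand[sample.int(length(cand), length(rows))]
    used[take] <- TRUE
    m_rows <- c(m_rows, rows)
    m_ctrl <- c(m_ctrl, take)
  }
  case_rows <- match(cases$subject_id[m_rows], rownames(prep$wide))
  ctrl_rows <- match(ctrl$subject_id[m_ctrl], rownames(prep$wide))
  base_case <- cases$baseline_year[m_rows]
  base_ctrl <- ctrl$birth_year[m_ctrl] + cases$age[m_rows]

  cum <- c(lb_sum(prep, case_rows, base_case, L),
           lb_sum(prep, ctrl_rows, base_ctrl, L))
  y <- rep(c(1L, 0L), each = length(m_rows))
  top <- top_quintile_split(cum)
  effect <- mean(y[top == 1]) - mean(y[top == 0])
  p <- t.test(y[top == 1], y[top == 0])$p.value
  tibble::tibble(lookback_years = L, effect = effect, p_value = p,
                 n_cases = length(m_rows), n_controls = length(m_ctrl),
                 n_excluded_cases = n_excluded)
}

#' One matched lookback trial
#'
#' Draws a fresh 1:1 matched case-control study from a longitudinal
#' cohort: cases are first-event subjects with at least two surveys
#' through the event year and full coverage of the lookback span; each is
#' matched without replacement to an event-free control of the same sex
#' and age at baseline, the control's baseline year chosen so its age
#' matches the case's. The effect is the risk difference in event
#' proportion between the top cumulative-exposure quintile and the rest,
#' with a two-sided Welch t-test p-value.
#'
#' @param cohort A [gen_longitudinal_cohort()] tibble.
#' @param lookback_years Window length L (1..4 in the canonical sweep).
#' @param seed Optional seed (matching is random).
#' @return One-row tibble: `lookback_years`, `effect`, `p_value`,
#'   `n_cases`, `n_controls`, `n_excluded_cases`.
#' @examples
#' \donttest{
#' lc <- gen_longitudinal_cohort(generator_params(n_subjects = 3000))
#' lookback_trial(lc, 1, seed = 1)
#' }
#' @export
lookback_trial <- function(cohort, lookback_years, seed = NULL) {
  seed_rng(seed)
  lb_trial_core(lb_prepare(cohort), as.integer(lookback_years))
}

#' Lookback sweep with FDR-flagged significance
#'
#' Repeats [lookback_trial()] `n_trials` times (fresh matching each time)
#' for every lookback length, normalizes each trial's effect by the mean
#' 1-year effect of the same sweep (so the mean normalized 1-year effect
#' is exactly 1), and applies Benjamini-Hochberg FDR correction across the
#' full L x trial grid of p-values.
#'
#' @param cohort A [gen_longitudinal_cohort()] tibble.
#' @param lookbacks Integer vector of lookback lengths (default 1:4).
#' @param n_trials Trials per lookback length (default 200).
#' @param alpha FDR level for the significance flag.
#' @param seed Seed fixing the whole sweep.
#' @return A list of class `tb_lookback`: `results` (one row per trial:
#'   effect, `normalized_effect`, p-value, `significant_fdr`, trial index)
#'   and `summary` (per L: mean normalized effect, mean absolute
#'   normalized effect, fraction significant).
#' @examples
#' \donttest{
#' lc <- gen_longitudinal_cohort(generator_params(n_subjects = 3000))
#' sw <- lookback_sweep(lc, n_trials = 10, seed = 1)
#' sw$summary
#' }
#' @export
lookback_sweep <- function(cohort, lookbacks = 1:4, n_trials = 200L,
                           alpha = 0.05, seed = NULL) {
  if (n_trials < 2) {
    abort("`n_trials` must be at least 2.", class = "tempbias_invalid_parameter")
  }
  if (!1 %in% lookbacks) {
    abort("`lookbacks` must include 1 (the normalization reference).",
          class = "tempbias_invalid_parameter")
  }
  seed_rng(seed)
  prep <- lb_prepare(cohort)
  res <- vector("list", length(lookbacks) * n_trials)
  i <- 0L
  for (L in as.integer(lookbacks)) {
    for (tr in seq_len(n_trials)) {
      i <- i + 1L
      row <- lb_trial_core(prep, L)
      row$trial <- tr
      res[[i]] <- row
    }
  }
  results <- dplyr::bind_rows(res)
  ref <- mean(results$effect[results$lookback_years == 1])
  results$normalized_effect <- results$effect / ref
  results$p_adjusted <- p.adjust(results$p_value, method = "BH")
  results$significant_fdr <- results$p_adjusted < alpha

  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$lookback_years),
    mean_normalized_effect = mean(.data$normalized_effect),
    mean_abs_normalized_effect = mean(abs(.data$normalized_effect)),
    frac_significant = mean(.data$significant_fdr),
    mean_effect = mean(.data$effect),
    .groups = "drop"
  )
  structure(list(results = results, summary = summary, alpha = alpha,
                 n_trials = n_trials, seed = seed),
            class = "tb_lookback")
}

#' @export
print.tb_lookback <- function(x, ...) {
  cat(sprintf("<tb_lookback> %d trials per lookback, FDR level %.2f\n",
              x$n_trials, x$alpha))
  print(x$summary)
  invisible(x)
}
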