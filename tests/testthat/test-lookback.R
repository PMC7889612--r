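test_that("cumulative exposure sums the lookback span and flags gaps", {
  lc <- tibble::tibble(subject_id = "a", year = 2001:2003,
                       exposure = c(2, 3, 4))
  b <- tibble::tibble(subject_id = "a", baseline_year = 2003)
  expect_equal(cumulative_exposure(lc, b, 3)$cum_exposure, 9)
  expect_equal(cumulative_exposure(lc, b, 1)$cum_exposure, 4)
  expect_equal(cumulative_exposure(lc, b, 2)$cum_exposure, 7)
  gap <- cumulative_exposure(lc, b, 4)   # span reaches a missing year
  expect_true(is.na(gap$cum_exposure))
  expect_false(gap$complete)
  expect_error(cumulative_exposure(lc, b, 0), class = "tempbias_invalid_parameter")
})

test_that("the top-quintile split follows the 80th-percentile cut with ties up", {
  expect_equal(sum(top_quintile_split(1:100)), 20)
  expect_equal(which(top_quintile_split(1:100) == 1), 81:100)
  expect_equal(which(top_quintile_split(1:10) == 1), 9:10)
  # heavy ties at the cut: everyone at the cut is labeled 1
  tied <- c(1, 2, 3, rep(8, 7))
  expect_equal(sum(top_quintile_split(tied)), 7)
  expect_gt(mean(top_quintile_split(tied)), 0.2)
  expect_error(top_quintile_split(rep(5, 10)),
               class = "tempbias_degenerate_split")
  expect_error(top_quintile_split(1:4), class = "tempbias_invalid_input")
})

test_that("a lookback trial is reproducible and sized by its matching", {
  lc <- gen_longitudinal_cohort(generator_params(n_subjects = 5000),
                                seed = 301)
  a <- lookback_trial(lc, 1, seed = 302)
  b <- lookback_trial(lc, 1, seed = 302)
  expect_identical(a, b)
  expect_equal(a$n_cases, a$n_controls)
  expect_gte(a$p_value, 0)
  expect_lte(a$p_value, 1)
})

test_that("a null generator is calibrated: uniform p-values, nominal type-I error", {
  # replicates must draw fresh cohorts: trials over one cohort share its
  # case realization and are therefore correlated
  p <- generator_params(n_subjects = 2500, effect_coef = 0,
                        hazard_intercept = -3.3)
  pvals <- vapply(seq_len(400), function(i) {
    lc <- gen_longitudinal_cohort(p, seed = 500 + i)
    lookback_trial(lc, 1, seed = 10500 + i)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  mc_se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * mc_se)
})

test_that("a protective recent-year effect is detected with a consistent sign", {
  lc <- gen_longitudinal_cohort(generator_params(n_subjects = 10000),
                                seed = 305)
  set.seed(306)
  prep <- tempbias:::lb_prepare(lc)
  eff <- vapply(seq_len(200), function(i) {
    tempbias:::lb_trial_core(prep, 1L)$effect
  }, numeric(1))
  expect_gte(mean(eff < 0), 0.95)
})

test_that("the sweep self-normalizes and applies FDR across the whole grid", {
  lc <- gen_longitudinal_cohort(generator_params(n_subjects = 6000),
                                seed = 307)
  sw <- lookback_sweep(lc, lookbacks = 1:2, n_trials = 10, seed = 308)
  expect_equal(
    sw$summary$mean_normalized_effect[sw$summary$lookback_years == 1], 1,
    tolerance = 1e-12)
  expect_equal(nrow(sw$results), 20)
  expect_equal(sw$results$p_adjusted, p.adjust(sw$results$p_value, "BH"))
  expect_error(lookback_sweep(lc, lookbacks = 2:3, n_trials = 5, seed = 1),
               class = "tempbias_invalid_parameter")
})
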