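test_that("the baseline fit is null when the arms share a law and positive otherwise", {
  law <- lognormal_params(log(55), 0.5)
  b0 <- baseline_effect(law, law, n_per_arm = 20000, seed = 61)
  expect_lt(abs(b0$coefficient / b0$se), 3)
  laws <- standin_laws(generator_params())
  b1 <- baseline_effect(laws$case, laws$control, n_per_arm = 20000, seed = 62)
  expect_gt(b1$coefficient, 0)
  expect_gt(b1$coefficient / b1$se, 3)
})

test_that("the logistic fit matches a direct maximum-likelihood oracle", {
  # discrete overlapping design (both classes present at x = 1 and x = 2,
  # so the MLE is finite)
  x <- c(rep(0, 100), rep(1, 80), rep(2, 20), rep(1, 20), rep(2, 80))
  y <- c(rep(0, 200), rep(1, 100))
  fit <- tempbias:::fit_logit(x, y)
  expect_equal(fit$coefficient, logit_mle_oracle(x, y), tolerance = 1e-5)
})

test_that("degenerate trajectories leave the baseline untouched", {
  laws <- standin_laws(generator_params())
  b0 <- baseline_effect(laws$case, laws$control, n_per_arm = 20000, seed = 71)
  # heaviside with the impulse essentially at t = 0: no pre-jump mass
  pr <- prospective_trial(laws$case, laws$control, shape = "heaviside",
                          method = "percentile_matching", n_per_arm = 20000,
                          seed = 71, shape_param = 1e-9)
  expect_lt(abs(pr$coefficient - b0$coefficient),
            4 * sqrt(pr$se^2 + b0$se^2))
  # a vanishing percent shift makes start == end up to rounding
  pr2 <- prospective_trial(laws$case, laws$control, shape = "linear",
                           method = "percent_shift", n_per_arm = 20000,
                           seed = 71, shift_fraction = 1e-9)
  expect_lt(abs(pr2$coefficient - b0$coefficient),
            4 * sqrt(pr2$se^2 + b0$se^2))
})

test_that("a mid-trajectory impulse halves the effect", {
  laws <- standin_laws(generator_params())
  res <- relative_effect_summary(
    laws$case, laws$control,
    grid = tibble::tibble(method = "percentile_matching",
                          shape = "heaviside", shape_param = 0.5),
    n_reps = 10, n_per_arm = 20000, seed = 81
  )
  # the case arm becomes a (1-p):p mixture of case and control laws, so
  # the group gap (and the near-linear-regime coefficient) scales by 1-p
  expect_lt(abs(res$ratio_mean - 0.5), 0.025)
})

test_that("attenuation weakens monotonically as the impulse moves earlier", {
  laws <- standin_laws(generator_params())
  res <- relative_effect_summary(
    laws$case, laws$control,
    grid = tibble::tibble(method = "weighted_sampling", shape = "heaviside",
                          shape_param = c(0.1, 0.01, 0.001)),
    n_reps = 10, n_per_arm = 10000, seed = 82
  )
  r <- res$ratio_mean[order(res$shape_param, decreasing = TRUE)]
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 1 + 3 * (res$ci_hi - res$ci_lo) / 4))
})

test_that("the effect-grid summary is deterministic given a seed", {
  laws <- standin_laws(generator_params())
  grid <- tibble::tibble(method = "percent_shift", shape = "linear",
                         shape_param = NA)
  a <- relative_effect_summary(laws$case, laws$control, grid = grid,
                               n_reps = 3, n_per_arm = 2000, seed = 91)
  b <- relative_effect_summary(laws$case, laws$control, grid = grid,
                               n_reps = 3, n_per_arm = 2000, seed = 91)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_error(relative_effect_summary(laws$case, laws$control, grid = grid,
                                       n_reps = 1, seed = 1),
               class = "tempbias_invalid_parameter")
})
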