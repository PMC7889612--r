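test_that("trajectory families evaluate to their closed forms", {
  expect_equal(trajectory_value(trajectory_spec(10, 20, "linear"), 0.5), 15)
  hs <- trajectory_spec(10, 20, "heaviside", 0.1)
  expect_equal(trajectory_value(hs, 0.05), 10)
  expect_equal(trajectory_value(hs, 0.10), 20)  # right-continuous at the jump
  lg <- trajectory_spec(10, 20, "logarithmic", 99)
  expect_equal(trajectory_value(lg, 0.5),
               10 + 10 * log(1 + 99 * 0.5) / log(100))
  # logistic midpoint is the exact middle by symmetry
  expect_equal(trajectory_value(trajectory_spec(10, 20, "logistic", 10), 0.5),
               15)
})

test_that("all shapes anchor their endpoints and are monotone", {
  set.seed(201)
  shapes <- list(linear = NA, logistic = NULL, logarithmic = NULL,
                 heaviside = NULL)
  grid <- seq(0, 1, length.out = 201)
  for (i in 1:25) {
    start <- runif(1, 1, 50)
    end <- start + runif(1, 0, 100)
    for (shape in names(shapes)) {
      sp <- switch(shape, linear = NULL, logistic = runif(1, 0.5, 30),
                   logarithmic = runif(1, 0.5, 500),
                   heaviside = runif(1, 0.01, 0.99))
      spec <- trajectory_spec(start, end, shape, sp)
      v <- trajectory_value(spec, grid)
      expect_equal(v[1], start, tolerance = 1e-12)
      expect_equal(v[length(v)], end, tolerance = 1e-12)
      expect_true(all(diff(v) >= -1e-12))
    }
  }
})

test_that("logarithmic dominates linear which dominates early logistic", {
  t <- seq(0.001, 0.999, length.out = 101)
  lin <- trajectory_value(trajectory_spec(10, 20, "linear"), t)
  lg <- trajectory_value(trajectory_spec(10, 20, "logarithmic", 99), t)
  lo <- trajectory_value(trajectory_spec(10, 20, "logistic", 10), t)
  expect_true(all(lg >= lin - 1e-12))
  expect_true(all(lo[t < 0.5] <= lin[t < 0.5] + 1e-12))
})

test_that("times outside the unit interval and bad parameters are rejected", {
  spec <- trajectory_spec(10, 20, "linear")
  expect_error(trajectory_value(spec, -0.1), class = "tempbias_invalid_input")
  expect_error(trajectory_value(spec, 1.1), class = "tempbias_invalid_input")
  expect_error(trajectory_spec(0, 20, "linear"), class = "tempbias_invalid_input")
  expect_error(trajectory_spec(10, 20, "heaviside", 1.5),
               class = "tempbias_invalid_parameter")
  expect_error(trajectory_spec(10, 20, "logistic", -1),
               class = "tempbias_invalid_parameter")
})

test_that("uniform-time sampling has the right marginal behaviour", {
  # heaviside: share of draws at the start value is the impulse fraction
  p <- 0.3
  draws <- sample_case_observation(trajectory_spec(10, 20, "heaviside", p),
                                   n = 100000, seed = 41)
  mc_se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(mean(draws == 10) - p), 3 * mc_se)
  # degenerate trajectory
  same <- sample_case_observation(trajectory_spec(15, 15, "linear"),
                                  n = 100, seed = 42)
  expect_true(all(same == 15))
  # linear: mean is the midpoint
  lin <- sample_case_observation(trajectory_spec(10, 20, "linear"),
                                 n = 100000, seed = 43)
  expect_lt(abs(mean(lin) - 15), 3 * sd(lin) / sqrt(1e5))
})

test_that("percent-shift and percentile-matching imputations are exact", {
  ctrl <- lognormal_params(log(51), 1)
  cs <- lognormal_params(log(60), 1)
  expect_equal(impute_start_value(100, ctrl, cs, "percent_shift"), 85)
  expect_equal(impute_start_value(60, ctrl, cs, "percentile_matching"), 51)
  expect_error(impute_start_value(-1, ctrl, cs, "percent_shift"),
               class = "tempbias_invalid_input")
})

test_that("percentile matching maps the case law onto the control law", {
  ctrl <- lognormal_params(log(51), 0.8)
  cs <- lognormal_params(log(60), 1.1)
  set.seed(51)
  ends <- rlnorm(10000, cs$mu, cs$sigma)
  starts <- impute_start_value(ends, ctrl, cs, "percentile_matching")
  ks <- suppressWarnings(ks.test(starts, plnorm, ctrl$mu, ctrl$sigma))
  expect_gt(ks$p.value, 0.01)
})

test_that("weighted sampling equals the rejection-sampling law below the case value", {
  ctrl <- lognormal_params(log(51), 1)
  cs <- lognormal_params(log(60), 1)
  draws <- impute_start_value(rep(60, 10000), ctrl, cs, "weighted_sampling",
                              seed = 52)
  expect_true(all(draws < 60))
  set.seed(53)
  oracle <- rejection_start_oracle(10000, 60, ctrl)
  ks <- suppressWarnings(ks.test(draws, oracle))
  expect_gt(ks$p.value, 0.01)
})
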