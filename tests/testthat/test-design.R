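test_that("exact matching pairs every case in a single shared stratum", {
  p <- generator_params(n_cases = 10, n_controls = 10,
                        control_pool_factor = 1,
                        age_range = c(30L, 30L), n_regions = 1L)
  cc <- gen_claims_cohort(p, seed = 201)
  m <- match_controls(cc, seed = 202)
  expect_equal(sum(m$patients$is_case == 1), 10)
  expect_equal(sum(m$patients$is_case == 0), 10)
  expect_equal(attr(m, "n_dropped"), 0L)
  # matched controls inherit their case's delivery month as baseline
  expect_setequal(m$patients$baseline_month[m$patients$is_case == 0],
                  m$patients$baseline_month[m$patients$is_case == 1])
})

test_that("a case with no control in its stratum is dropped and counted", {
  pts <- tibble::tibble(
    patient_id = c("c1", "c2", "c3", "c4", "c5", "c6", "k1", "k2", "k3",
                   "k4", "k5"),
    age = c(25L, 30L, 30L, 30L, 30L, 30L, 25L, 30L, 30L, 30L, 30L),
    region = "R01",
    delivery_month = c(5L, 6L, 7L, 8L, 9L, 10L, rep(NA_integer_, 5))
  )
  # c1 (age 25) matches k1; the five age-30 cases compete for four controls
  cohort <- manual_claims_cohort(pts)
  expect_warning(m <- match_controls(cohort, seed = 203), "dropped")
  expect_equal(attr(m, "n_dropped"), 1L)
  expect_equal(sum(m$patients$is_case == 1), 5)
})

test_that("matching errors out when too many cases cannot be paired", {
  pts <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:12),
    age = c(rep(20L, 10), 40L, 40L),
    region = "R01",
    delivery_month = c(rep(5L, 10), NA_integer_, NA_integer_)
  )
  expect_error(suppressWarnings(match_controls(manual_claims_cohort(pts),
                                               seed = 204)),
               class = "tempbias_matching_error")
})

test_that("matched arms share identical age and region frequency tables", {
  cc <- gen_claims_cohort(generator_params(n_cases = 300, n_controls = 300),
                          seed = 205)
  m <- suppressWarnings(match_controls(cc, seed = 206))
  cases <- m$patients[m$patients$is_case == 1, ]
  ctrls <- m$patients[m$patients$is_case == 0, ]
  expect_equal(table(cases$age, cases$region), table(ctrls$age, ctrls$region))
})

test_that("windows follow the anchoring rules with year-boundary exclusions", {
  pts <- tibble::tibble(patient_id = sprintf("p%02d", 2:12), age = 30L,
                        region = "R01", delivery_month = 2:12,
                        baseline_month = 2:12, is_case = 1L)
  ei <- assign_window(pts, study_design("event_indexed", offset_months = 3))
  # May delivery -> February window
  expect_equal(ei$window_month[ei$baseline_month == 5], 2L)
  # offset reaching into the previous year -> excluded
  expect_false(any(ei$window_valid[ei$baseline_month %in% c(2, 3)]))
  expect_equal(ei$window_month[ei$window_valid],
               (4:12) - 3L)
  cf <- assign_window(pts, study_design("calendar_fixed", fixed_month = 1))
  expect_true(all(cf$window_month == 1L))
  expect_true(all(cf$window_valid))
})

test_that("feature extraction binarizes codes and keeps age", {
  pts <- tibble::tibble(patient_id = c("a", "b"), age = c(31L, 35L),
                        region = "R01", delivery_month = c(8L, NA),
                        baseline_month = c(8L, 8L), is_case = c(1L, 0L))
  cohort <- manual_claims_cohort(pts)
  cohort$events <- tibble::tibble(
    patient_id = c("a", "a", "a"), month = c(5L, 5L, 6L),
    code = c("B01", "B01", "B02"), code_class = "background"
  )
  w <- assign_window(pts, study_design("event_indexed", offset_months = 3))
  f <- extract_features(cohort, w)
  expect_equal(f$age, c(31L, 35L))
  expect_equal(f$label, c(1L, 0L))
  # code occurring twice in the window is still an indicator of 1
  expect_equal(f$B01[f$patient_id == "a"], 1L)
  expect_equal(f$B02[f$patient_id == "a"], 0L)  # outside the window
  expect_equal(sum(f[f$patient_id == "b", -(1:4)]), 0L)
})

test_that("event-indexed windows see more gestational signal than January", {
  cc <- gen_claims_cohort(generator_params(n_cases = 400, n_controls = 400),
                          seed = 207)
  m <- suppressWarnings(match_controls(cc, seed = 208))
  gcols <- attr(m, "vocabulary")$code[attr(m, "vocabulary")$code_class ==
                                        "gestational"]
  f_ei <- extract_features(m, assign_window(m$patients,
                                            study_design("event_indexed")))
  f_cf <- extract_features(m, assign_window(m$patients,
                                            study_design("calendar_fixed")))
  oct_cases <- m$patients$patient_id[m$patients$is_case == 1 &
                                       m$patients$baseline_month == 10]
  sum_g <- function(f, ids) sum(f[f$patient_id %in% ids, gcols])
  expect_gt(sum_g(f_ei, oct_cases), sum_g(f_cf, oct_cases))
})

test_that("label-shuffled training scores at chance", {
  cc <- gen_claims_cohort(generator_params(n_cases = 1000, n_controls = 1000),
                          seed = 209)
  m <- suppressWarnings(match_controls(cc, seed = 210))
  shuffler <- function(x_train, y_train) {
    tempbias:::logistic_classifier(x_train, sample(y_train))
  }
  rs <- run_design_study(m, study_design("event_indexed"),
                         study_design("event_indexed"),
                         n_models = 6, classifier = shuffler, seed = 211)
  expect_lt(abs(mean(rs$auroc$auroc) - 0.5), 0.04)
})

test_that("without a time-varying signal all three designs are equivalent", {
  p <- generator_params(n_cases = 800, n_controls = 800,
                        gestational_rate = 0, gestational_rate_min = 0)
  m <- suppressWarnings(match_controls(gen_claims_cohort(p, seed = 212), seed = 213))
  ei <- study_design("event_indexed"); cf <- study_design("calendar_fixed")
  au <- vapply(list(list(ei, ei), list(ei, cf), list(cf, cf)), function(d) {
    mean(run_design_study(m, d[[1]], d[[2]], n_models = 4,
                          seed = 214)$auroc$auroc)
  }, numeric(1))
  # null AUROC sd per model at this evaluation size is ~0.03; means over
  # 4 models should sit near chance and near each other
  expect_true(all(abs(au - 0.5) < 0.06))
  expect_lt(max(au) - min(au), 0.06)
})

test_that("prediction collapses when event-indexed training meets calendar evaluation", {
  m <- suppressWarnings(match_controls(gen_claims_cohort(
    generator_params(n_cases = 800, n_controls = 800), seed = 215), seed = 216))
  ei <- study_design("event_indexed"); cf <- study_design("calendar_fixed")
  cc_cc <- run_design_study(m, ei, ei, n_models = 3, seed = 217)
  cc_co <- run_design_study(m, ei, cf, n_models = 3, seed = 217)
  co_co <- run_design_study(m, cf, cf, n_models = 3, seed = 217)
  expect_gt(mean(cc_cc$auroc$auroc), mean(co_co$auroc$auroc))
  expect_gt(mean(co_co$auroc$auroc), mean(cc_co$auroc$auroc))
  # evaluation patients are disjoint from training by construction; each
  # model evaluates ~20% of the cohort
  expect_equal(nrow(cc_co$scores),
               3 * ceiling(0.2 * nrow(m$patients)))
})

test_that("the design-contrast gap grows with the gestational ramp", {
  gaps <- vapply(c(0.5, 1.5, 3), function(rate) {
    p <- generator_params(n_cases = 700, n_controls = 700,
                          gestational_rate = rate)
    m <- suppressWarnings(match_controls(gen_claims_cohort(p, seed = 218),
                                           seed = 219))
    ei <- study_design("event_indexed"); cf <- study_design("calendar_fixed")
    a <- mean(run_design_study(m, ei, ei, n_models = 3, seed = 220)$auroc$auroc)
    b <- mean(run_design_study(m, ei, cf, n_models = 3, seed = 220)$auroc$auroc)
    a - b
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
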