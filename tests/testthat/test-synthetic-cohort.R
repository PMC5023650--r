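test_that("spec validation rejects bad fields by name", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(pf_params = c(mean = 127, sd = -1)), "pf_params")
  expect_error(cohort_spec(overall_mortality_target = 1.2),
               "overall_mortality_target")
  expect_error(cohort_spec(followup_horizon = -5), "followup_horizon")
  expect_error(generate_cohort(data.frame()), "cohort_spec")
})

test_that("flat mortality model reproduces its intercept probability", {
  spec <- cohort_spec(n_patients = 1e5, seed = 101,
                      mortality = mortality_model(qlogis(0.43), slope = 0),
                      overall_mortality_target = NULL)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 1e5)
  se <- sqrt(0.43 * 0.57 / 1e5)
  expect_lt(abs(mean(co$died_in_hospital) - 0.43), 3 * se)
})

test_that("same seed gives a byte-identical serialized cohort", {
  spec <- cohort_spec(n_patients = 500, seed = 7)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(spec), f1)
  write_cohort(generate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
  spec2 <- cohort_spec(n_patients = 500, seed = 8)
  f3 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(spec2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("positive slope yields strictly increasing mortality by score level", {
  co <- make_linear_cohort(1e5, seed = 31, slope = 0.6)
  sc <- score_cohort(co)
  rate <- tapply(sc$died_in_hospital, sc$apps, mean)
  expect_identical(as.integer(names(rate)), 3:9)
  expect_true(all(diff(rate) > 0))
})

test_that("cohort records satisfy the physiological invariants", {
  co <- generate_cohort(cohort_spec(n_patients = 2000, seed = 12))
  expect_true(all(co$age >= 18 & co$age <= 100))
  expect_true(all(co$pf_ratio >= 30 & co$pf_ratio <= 200))
  expect_true(all(co$pmax >= 10 & co$pmax <= 50))
  expect_true(all(co$followup_days > 0 &
                    co$followup_days <= 60 + 1e-9))
  # death implies the event is observed within the horizon
  expect_true(all(co$event_observed[co$died_in_hospital]))
  expect_true(all(!co$event_observed[!co$died_in_hospital]))
})

test_that("logistic fit on the true score recovers the mechanism within 3 SE", {
  spec <- cohort_spec(n_patients = 1e4, seed = 55,
                      mortality = mortality_model(-2.8, slope = 0.4),
                      overall_mortality_target = NULL)
  sc <- score_cohort(generate_cohort(spec))
  fit <- glm(died_in_hospital ~ apps, family = binomial(), data = sc)
  est <- coef(summary(fit))
  expect_lt(abs(est["apps", "Estimate"] - 0.4),
            3 * est["apps", "Std. Error"])
  expect_lt(abs(est["(Intercept)", "Estimate"] - (-2.8)),
            3 * est["(Intercept)", "Std. Error"])
})

test_that("single-variable margin calibration reproduces published rates", {
  # original age strata
  sp <- calibrate_spec_to_margins(list(age = c(0.264, 0.439, 0.480)),
                                  cohort_spec(n_patients = 1e5, seed = 21))
  cal <- attr(sp, "calibration")
  expect_lt(cal$max_abs_deviation, 1e-6)   # closed-form exact
  sc <- score_cohort(generate_cohort(sp))
  st <- stratify_cohort(sc, "age")
  expect_true(all(abs(st$mortality_pct / 100 -
                        c(0.264, 0.439, 0.480)) < 0.03))
  # recalibrated Pmax strata
  sp2 <- calibrate_spec_to_margins(
    list(pmax = c(0.331, 0.45, 0.553)),
    cohort_spec(n_patients = 1e5, seed = 22,
                definition = builtin_definition("recalibrated")))
  sc2 <- score_cohort(generate_cohort(sp2),
                      builtin_definition("recalibrated"))
  st2 <- stratify_cohort(sc2, "pmax")
  expect_true(all(abs(st2$mortality_pct / 100 -
                        c(0.331, 0.45, 0.553)) < 0.03))
})

test_that("equal margin targets recover a flat (zero-offset) mechanism", {
  sp <- calibrate_spec_to_margins(list(age = c(0.4, 0.4, 0.4)),
                                  cohort_spec(n_patients = 100, seed = 1))
  off <- attr(sp, "calibration")$offsets$age
  expect_lt(max(abs(off)), 1e-4)
})

test_that("margin targets are validated and joint inconsistency is refused", {
  expect_error(calibrate_spec_to_margins(list(age = c(0.2, 1.4, 0.5))),
               "proportions")
  expect_error(calibrate_spec_to_margins(list(weight = c(0.2, 0.3, 0.4))),
               "named list")
  # the three published triples jointly imply different overall
  # mortalities under the fixed predictor marginals -> infeasible
  expect_error(
    calibrate_spec_to_margins(published_margin_targets("original")),
    "infeasible")
})

test_that("raising the slope never lowers the high-score stratum death rate", {
  high_rate <- vapply(c(0, 0.3, 0.6, 0.9), function(s) {
    co <- make_linear_cohort(1e5, seed = 77, slope = s)
    sc <- score_cohort(co)
    mean(sc$died_in_hospital[sc$apps >= 8])
  }, numeric(1))
  expect_true(all(diff(high_rate) >= 0))
})

test_that("cohort spec round-trips through its config file", {
  sp <- calibrate_spec_to_margins(list(age = c(0.264, 0.439, 0.480)),
                                  cohort_spec(n_patients = 300, seed = 9))
  path <- tempfile(fileext = ".yaml")
  write_cohort_spec(sp, path)
  sp2 <- read_cohort_spec(path)
  co1 <- generate_cohort(sp)
  co2 <- generate_cohort(sp2)
  expect_equal(co1$age, co2$age, tolerance = 1e-9)
  expect_identical(co1$died_in_hospital, co2$died_in_hospital)
})
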