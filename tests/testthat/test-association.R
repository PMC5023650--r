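test_that("count reconstruction uses half-away-from-zero rounding", {
  s <- reconstruct_counts(196, 43.9)
  expect_identical(s$deaths, 86L)
  expect_identical(s$survivors, 110L)
  s2 <- reconstruct_counts(72, 26.4)
  expect_identical(s2$deaths, 19L)
  expect_identical(s2$survivors, 53L)
  expect_identical(reconstruct_counts(50, 0)$deaths, 0L)
  # 0.5 rounds up, where round-half-even would go down
  expect_identical(reconstruct_counts(10, 25)$deaths, 3L)
})

test_that("reconstructed mortality is within the rounding half-width", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(10:500, 1)
    pct <- runif(1, 0, 100)
    s <- reconstruct_counts(n, pct)
    expect_lte(abs(s$mortality_pct - pct), 100 / (2 * n) + 1e-9)
  }
})

test_that("odds ratios reproduce published rows and the identity case", {
  o <- odds_ratio(reconstruct_counts(196, 43.9), reconstruct_counts(72, 26.4))
  expect_equal(round(o$point, 2), 2.18)
  expect_equal(round(o$lower, 2), 1.20)
  expect_equal(round(o$upper, 2), 3.95)
  o2 <- odds_ratio(reconstruct_counts(65, 56.9), reconstruct_counts(239, 36.4))
  expect_equal(round(o2$point, 2), 2.31)
  same <- stratum("x", 100, 40)
  oi <- odds_ratio(same, same)
  expect_equal(oi$point, 1)
  expect_false(oi$corrected)
})

test_that("zero cells trigger a flagged continuity-corrected estimate", {
  o <- odds_ratio(stratum("a", 20, 0), stratum("b", 20, 5))
  expect_true(o$corrected)
  expect_true(is.finite(o$point) && o$point > 0)
  expect_true(o$lower <= o$point && o$point <= o$upper)
})

test_that("scaling all cells leaves the OR fixed and narrows the interval", {
  a <- stratum("a", 100, 40); b <- stratum("b", 120, 30)
  o1 <- odds_ratio(a, b)
  o10 <- odds_ratio(stratum("a", 1000, 400), stratum("b", 1200, 300))
  expect_equal(o10$point, o1$point, tolerance = 1e-12)
  expect_lt(o10$upper - o10$lower, o1$upper - o1$lower)
})

test_that("Wald interval matches an independent log-odds recomputation", {
  set.seed(99)
  for (i in 1:100) {
    d1 <- sample(1:80, 1); s1 <- sample(1:80, 1)
    d0 <- sample(1:80, 1); s0 <- sample(1:80, 1)
    o <- odds_ratio(stratum("a", d1 + s1, d1), stratum("b", d0 + s0, d0))
    lo <- log(d1) - log(s1) - log(d0) + log(s0)
    se <- sqrt(1 / d1 + 1 / s1 + 1 / d0 + 1 / s0)
    z <- qnorm(0.975)
    expect_equal(o$lower, exp(lo - z * se), tolerance = 1e-10)
    expect_equal(o$upper, exp(lo + z * se), tolerance = 1e-10)
  }
  # and, more loosely, the glm route on one table
  fit <- glm(cbind(c(19, 86), c(53, 110)) ~ c(0, 1), family = binomial())
  o <- odds_ratio(stratum("a", 196, 86), stratum("b", 72, 19))
  expect_equal(log(o$point), unname(coef(fit)[2]), tolerance = 1e-6)
  expect_equal(o$log_se, sqrt(vcov(fit)[2, 2]), tolerance = 1e-6)
})

test_that("trend test flags published age strata and null cases correctly", {
  st <- strata_from_counts(c(72, 196, 171),
                           c(reconstruct_counts(72, 26.4)$deaths,
                             reconstruct_counts(196, 43.9)$deaths,
                             reconstruct_counts(171, 48)$deaths))
  expect_lt(trend_test(st)$p, 0.01)
  # two identical strata: no trend
  same <- strata_from_counts(c(100, 100), c(30, 30))
  expect_gt(trend_test(same)$p, 0.999)
  # degenerate outcome
  expect_warning(r <- trend_test(strata_from_counts(c(50, 50), c(0, 0))),
                 "degenerate")
  expect_identical(r$p, 1)
})

test_that("trend p agrees with a permutation oracle of the score statistic", {
  n <- c(40, 40, 40); d <- c(8, 12, 17)
  p_wald <- trend_test(strata_from_counts(n, d))$p
  p_ca <- trend_test(strata_from_counts(n, d),
                     method = "cochran_armitage")$p
  y <- unlist(mapply(function(ni, di) c(rep(1, di), rep(0, ni - di)), n, d))
  g <- rep(1:3, n)
  set.seed(1)
  t_obs <- sum(g * y)
  t_perm <- replicate(2e4, sum(g * sample(y)))
  p_perm <- mean(abs(t_perm - mean(t_perm)) >= abs(t_obs - mean(t_perm)))
  expect_lt(abs(p_wald - p_perm), 0.02)
  expect_lt(abs(p_ca - p_perm), 0.02)
  # strong monotone trend: all routes agree it is overwhelming
  n2 <- c(200, 200, 200); d2 <- c(20, 60, 100)
  y2 <- unlist(mapply(function(ni, di) c(rep(1, di), rep(0, ni - di)), n2, d2))
  g2 <- rep(1:3, n2)
  set.seed(2)
  t2 <- sum(g2 * y2)
  tp2 <- replicate(1e4, sum(g2 * sample(y2)))
  expect_lt(mean(abs(tp2 - mean(tp2)) >= abs(t2 - mean(tp2))), 1e-3)
  expect_lt(trend_test(strata_from_counts(n2, d2))$p, 1e-3)
})

test_that("cohort stratification matches targets and handles edge cases", {
  sp <- calibrate_spec_to_margins(
    list(age = c(0.264, 0.439, 0.480)),
    cohort_spec(n_patients = 2e4, seed = 33))
  sc <- score_cohort(generate_cohort(sp))
  st <- stratify_cohort(sc, "age")
  expect_identical(sum(st$n), 2e4L)
  expect_true(all(diff(st$mortality_pct) > 0))  # matches target ordering
  expect_lt(attr(st, "p_trend"), 1e-6)

  one <- score_cohort(data.frame(id = "p", age = 50, pf_ratio = 120,
                                 pmax = 25, died_in_hospital = FALSE))
  st1 <- stratify_cohort(one, "age")
  expect_identical(sum(st1$n > 0), 1L)
  expect_true(any(st1$flagged))

  # all ages in the reference band: no estimable ORs, flagged
  ref_only <- score_cohort(data.frame(
    id = paste0("p", 1:20), age = runif(20, 20, 40),
    pf_ratio = runif(20, 60, 190), pmax = runif(20, 15, 45),
    died_in_hospital = rep(c(TRUE, FALSE), 10)))
  str <- stratify_cohort(ref_only, "age")
  expect_true(all(is.na(str$or[2:3])))
  expect_true(all(str$flagged[2:3]))
})

test_that("published strata tables ship as printed, including the Pmax gap", {
  for (which in c("original", "recalibrated")) {
    tab <- apps_published_strata(which)
    expect_identical(sum(tab$n[tab$variable == "age"]), 439L)
    expect_identical(sum(tab$n[tab$variable == "pf_ratio"]), 439L)
    # 24 patients unaccounted in the printed Pmax strata
    expect_identical(sum(tab$n[tab$variable == "pmax"]), 415L)
  }
})
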