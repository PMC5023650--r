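test_that("degenerate Kaplan-Meier cases are exact", {
  allcens <- km_estimate(c(3, 7, 12), c(FALSE, FALSE, FALSE))
  expect_true(all(allcens$survival == 1))
  one <- km_estimate(5, TRUE)
  expect_equal(one$survival[one$time == 0], 1)
  expect_equal(one$survival[one$time == 5], 0)
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
  expect_error(km_estimate(c(1, -2), c(TRUE, TRUE)), "nonnegative")
})

test_that("product-limit values match the hand-computed mixed-ties fixture", {
  # 10 subjects; at t=2 an event and a censoring coincide (event first),
  # likewise at t=3 (2 events, 1 censoring) and t=5.
  # Hand computation: S(1)=9/10; S(2)=9/10*8/9=4/5; at t=3 risk set is 7,
  # S(3)=4/5*5/7=4/7; t=4 censoring only; at t=5 risk set 3, S(5)=4/7*2/3.
  km <- km_estimate(c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6),
                    c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
                      TRUE, FALSE, FALSE))
  sv <- function(t) km$survival[km$time == t]
  expect_equal(sv(1), 9 / 10, tolerance = 1e-12)
  expect_equal(sv(2), 4 / 5, tolerance = 1e-12)
  expect_equal(sv(3), 4 / 7, tolerance = 1e-12)
  expect_equal(sv(5), 8 / 21, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(diff(km$at_risk[-1]) <= 0))
})

test_that("without censoring the KM curve is the empirical survival function", {
  set.seed(13)
  t <- round(rexp(60, 0.1), 2)
  km <- km_estimate(t, rep(TRUE, 60))
  for (tt in km$time[-1]) {
    expect_equal(km$survival[km$time == tt], mean(t > tt),
                 tolerance = 1e-12)
  }
})

test_that("log-rank is null on copied strata and errors on empty ones", {
  s <- list(times = c(2, 4, 6, 8), events = c(TRUE, TRUE, FALSE, TRUE))
  lr <- logrank(list(a = s, b = s))
  expect_lt(lr$statistic, 1e-10)
  expect_gt(lr$p, 0.999)
  expect_identical(lr$df, 1L)
  expect_error(logrank(list(a = s, b = list(times = numeric(0),
                                            events = logical(0)))),
               "zero subjects")
})

test_that("log-rank p agrees with a label-permutation oracle", {
  set.seed(5)
  t1 <- rexp(30, 1); t2 <- rexp(30, 2)
  lr <- logrank(list(a = list(times = t1, events = rep(TRUE, 30)),
                     b = list(times = t2, events = rep(TRUE, 30))))
  allt <- c(t1, t2); lab <- rep(c("a", "b"), each = 30)
  set.seed(6)
  perm <- replicate(1000, {
    l <- sample(lab)
    survival::survdiff(survival::Surv(allt, rep(TRUE, 60)) ~ l)$chisq
  })
  expect_lt(abs(mean(perm >= lr$statistic) - lr$p), 0.025)
})

test_that("log-rank detects a threefold hazard ratio almost always", {
  hits <- vapply(1:100, function(s) {
    set.seed(7000 + s)
    a <- rexp(500, 1); b <- rexp(500, 3)
    logrank(list(a = list(times = a, events = rep(TRUE, 500)),
                 b = list(times = b, events = rep(TRUE, 500))))$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("log-rank is invariant to increasing time transforms", {
  set.seed(17)
  a <- rexp(80, 1); b <- rexp(80, 1.8)
  ea <- runif(80) < 0.8; eb <- runif(80) < 0.8
  base <- logrank(list(a = list(times = a, events = ea),
                       b = list(times = b, events = eb)))
  trans <- logrank(list(a = list(times = sqrt(a), events = ea),
                        b = list(times = sqrt(b), events = eb)))
  expect_equal(trans$statistic, base$statistic, tolerance = 1e-10)
})

test_that("score-category partitions are validated and exhaustive", {
  sc <- score_cohort(make_linear_cohort(1500, seed = 21, slope = 0.9))
  for (edges in list(list(3:4, 5:7, 8:9), list(3, 4:7, 8:9))) {
    strata <- stratify_by_category(sc, edges)
    expect_identical(sum(vapply(strata, nrow, integer(1))), 1500L)
  }
  expect_error(stratify_by_category(sc, list(3:5, 5:7, 8:9)), "partition")
  expect_error(stratify_by_category(sc, list(3:4, 6:7, 8:9)), "partition")
})

test_that("higher score categories have lower survival curves throughout", {
  sc <- score_cohort(make_linear_cohort(6000, seed = 29, slope = 0.9))
  kb <- km_by_category(sc, list(3:4, 5:7, 8:9))
  expect_identical(names(kb$curves), c("3-4", "5-7", "8-9"))
  expect_lt(kb$logrank$p, 0.001)
  expect_identical(kb$logrank$df, 2L)
  fns <- lapply(kb$curves, function(cv)
    stepfun(cv$time[-1], cv$survival))
  grid <- seq(5, 55, by = 5)
  expect_true(all(fns[["5-7"]](grid) <= fns[["3-4"]](grid)))
  expect_true(all(fns[["8-9"]](grid) <= fns[["5-7"]](grid)))
})

test_that("curve export writes one row per stratum-time", {
  sc <- score_cohort(make_linear_cohort(400, seed = 30))
  kb <- km_by_category(sc)
  path <- tempfile(fileext = ".csv")
  write_km_curves(kb$curves, path)
  out <- read.csv(path)
  expect_identical(sort(unique(out$stratum)), sort(names(kb$curves)))
  expect_identical(nrow(out),
                   sum(vapply(kb$curves, nrow, integer(1))))
})
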