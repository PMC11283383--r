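idx <- as.Date("2018-01-01")

test_that("TTNT composes next treatment and death, censoring otherwise", {
  r <- compute_ttnt(idx, as.Date(NA), idx + 300, idx + 600)
  expect_equal(r, list(time = 300, event = 1L))
  r <- compute_ttnt(idx, idx + 420, as.Date(NA), idx + 600)
  expect_equal(r, list(time = 420, event = 1L))
  r <- compute_ttnt(idx, as.Date(NA), as.Date(NA), idx + 600)
  expect_equal(r, list(time = 600, event = 0L))
  # index-day event gets a half-day to keep entry < exit
  r <- compute_ttnt(idx, idx, as.Date(NA), idx + 600)
  expect_equal(r$time, 0.5)

  r <- compute_ttd(idx, idx + 250, as.Date(NA), idx + 600)
  expect_equal(r, list(time = 250, event = 1L))
  r <- compute_ttd(idx, as.Date(NA), as.Date(NA), idx + 500)
  expect_equal(r, list(time = 500, event = 0L))
})

test_that("counting-process expansion splits at the hospitalization time", {
  ep <- data.frame(id = c("a", "b", "c"), time = c(400, 300, 200),
                   event = c(1L, 0L, 1L), x = c(1, 0, 1),
                   stringsAsFactors = FALSE)
  cp <- to_counting_process(ep, c(150, NA, 200))
  a <- cp[cp$id == "a", ]
  expect_equal(a$entry, c(0, 150))
  expect_equal(a$exit, c(150, 400))
  expect_equal(a$event, c(0L, 1L))
  expect_equal(a$hosp_event, c(0L, 1L))
  expect_equal(a$x, c(1, 1))
  # no hospitalization -> single row
  expect_equal(nrow(cp[cp$id == "b", ]), 1L)
  # hospitalization exactly at exit: left-continuous, no split
  cc <- cp[cp$id == "c", ]
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$hosp_event, 0L)
})

test_that("the product-limit estimator matches hand computation", {
  km <- kaplan_meier(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  expect_equal(km$curve$surv, c(4 / 5, 8 / 15, 4 / 15), tolerance = 1e-12)
  expect_equal(km$median, 4)
  # Greenwood variance at the first event time: S^2 * d/(n(n-d))
  expect_equal(km$curve$var_greenwood[1], 0.8^2 * 1 / (5 * 4))

  # all censored: flat curve, median not reached
  km <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))
  expect_equal(km_prob(km, c(1, 5)), c(1, 1))
  expect_true(is.na(km$median))

  # single subject with an event
  km <- kaplan_meier(5, 1)
  expect_equal(km_prob(km, 5), 0)

  expect_error(kaplan_meier(numeric(0), integer(0)),
               class = "cllclaims_fit_error")
})

test_that("KM with no censoring equals the empirical survivor function", {
  set.seed(9)
  t <- sample(1:20, 60, replace = TRUE)
  km <- kaplan_meier(t, rep(1, 60))
  for (tt in c(0.5, 3, 7.2, 19, 25)) {
    expect_equal(km_prob(km, tt), mean(t > tt), tolerance = 1e-12)
  }
})

test_that("the Cox fitter solves the analytic three-subject score equation", {
  d <- data.frame(exit = c(1, 2, 3), event = 1, x = c(1, 0, 1))
  f <- cox_fit(d, "x", ties = "breslow")
  expect_equal(f$coefficients$estimate, -0.5 * log(2), tolerance = 1e-9)
  expect_true(f$converged)
  # CI brackets the HR and HR = exp(estimate)
  expect_equal(f$coefficients$hr, exp(f$coefficients$estimate))
  expect_lt(f$coefficients$ci_low, f$coefficients$hr)
  expect_gt(f$coefficients$ci_high, f$coefficients$hr)
})

test_that("the score test at beta = 0 is the log-rank statistic", {
  set.seed(31)
  n <- 80
  t <- round(rexp(n, 0.05), 3) + runif(n) * 1e-6  # tie-free
  ev <- rbinom(n, 1, 0.7)
  x <- rbinom(n, 1, 0.5)
  f <- cox_fit(data.frame(exit = t, event = ev, x = x), "x")
  lr <- survival::survdiff(survival::Surv(t, ev) ~ x)
  expect_equal(f$score_test$chisq, lr$chisq, tolerance = 1e-8)
})

test_that("estimates agree with an independent Cox implementation", {
  set.seed(12)
  n <- 300
  d <- data.frame(exit = sample(1:40, n, TRUE), event = rbinom(n, 1, 0.6),
                  x = rbinom(n, 1, 0.4), z = rnorm(n))
  for (tie in c("efron", "breslow")) {
    f <- cox_fit(d, c("x", "z"), ties = tie)
    ref <- survival::coxph(survival::Surv(exit, event) ~ x + z, data = d,
                           ties = tie)
    expect_equal(f$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-7)
    expect_equal(f$coefficients$se, unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-7)
  }
})

test_that("a simulated hazard ratio of 2 is recovered within its CI", {
  b <- generate_survival_benchmark(
    2000, true_log_hr = c(x1 = log(2), x2 = 0, hosp = 0), seed = 77)
  f <- cox_fit(b$records, c("x1", "x2", "hosp"))
  hr <- f$coefficients$hr[f$coefficients$term == "x1"]
  expect_gt(hr, 1.8)
  expect_lt(hr, 2.2)
  expect_lt(f$coefficients$ci_low[1], 2)
  expect_gt(f$coefficients$ci_high[1], 2)
})

test_that("interval splitting at uninformative times leaves the fit unchanged", {
  set.seed(5)
  n <- 150
  ep <- data.frame(id = seq_len(n), time = rexp(n, 0.01) + 1,
                   event = rbinom(n, 1, 0.7), x = rbinom(n, 1, 0.5))
  plain <- cox_fit(ep, "x")
  # split every subject mid-follow-up; the hosp column stays 0 throughout
  cp <- to_counting_process(ep, ifelse(seq_len(n) %% 2 == 0,
                                       ep$time / 2, NA))
  split_fit <- cox_fit(cp, "x")
  expect_equal(split_fit$coefficients$estimate, plain$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(split_fit$coefficients$se, plain$coefficients$se,
               tolerance = 1e-10)
})

test_that("degenerate inputs raise typed fitting errors", {
  # no events
  expect_error(cox_fit(data.frame(exit = 1:3, event = 0, x = c(0, 1, 0)),
                       "x"),
               class = "cllclaims_fit_error")
  # constant covariate
  expect_error(cox_fit(data.frame(exit = 1:3, event = 1, x = 1), "x"),
               "degenerate", class = "cllclaims_fit_error")
  # monotone likelihood: the x = 1 subject always fails first
  d <- data.frame(exit = c(1, 2), event = 1, x = c(1, 0))
  expect_error(cox_fit(d, "x"), "monotone",
               class = "cllclaims_fit_error")
})
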