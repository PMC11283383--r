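test_that("configuration is validated", {
  expect_error(simulation_config(-1), class = "cllclaims_config_error")
  expect_error(simulation_config(10, disease_mix = c(CLL = 0.5, MCL = 0.2,
                                                     WM = 0.2, other = 0.2)),
               class = "cllclaims_config_error")
  expect_error(simulation_config(10, male_fraction = 1.2),
               class = "cllclaims_config_error")
  expect_error(
    simulation_config(10, event_hazards = c(next_treatment = -1, death = 0,
                                            hospitalization = 0)),
    class = "cllclaims_config_error")
})

test_that("an empty simulation yields an empty bundle and truth", {
  g <- generate_claims(simulation_config(0))
  expect_equal(nrow(g$bundle$patients), 0L)
  expect_equal(nrow(g$bundle$dispensations), 0L)
  expect_equal(nrow(g$truth$patients), 0L)
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- simulation_config(40, seed = 123)
  g1 <- generate_claims(cfg)
  g2 <- generate_claims(cfg)
  expect_identical(g1$bundle, g2$bundle)
  expect_identical(g1$truth, g2$truth)
  # and a different seed produces different data
  g3 <- generate_claims(simulation_config(40, seed = 124))
  expect_false(identical(g1$bundle$dispensations, g3$bundle$dispensations))
})

test_that("a degenerate disease mixture is honoured exactly", {
  cfg <- simulation_config(50, seed = 2,
                           disease_mix = c(CLL = 1, MCL = 0, WM = 0,
                                           other = 0))
  g <- generate_claims(cfg)
  expect_true(all(g$truth$patients$disease == "CLL"))
})

test_that("empirical prevalences track the configuration within 3 SE", {
  n <- 1500
  g <- generate_claims(simulation_config(n, seed = 8))
  tr <- g$truth$patients
  check <- function(obs_p, p) {
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs_p - p), 3 * se + 1e-12)
  }
  check(mean(tr$cv_comorbidity), 0.466)
  check(mean(tr$sex == "male"), 0.61)
  check(mean(tr$line == "L2plus"), 0.80)
  check(mean(tr$disease == "CLL"), 0.55)
})

test_that("every true regimen is backed by dispensations in the bundle", {
  g <- generate_claims(simulation_config(80, seed = 21))
  ib <- g$bundle$dispensations
  ib <- ib[ib$atc_code == "L01EL01", ]
  regs <- g$truth$regimens
  for (i in seq_len(nrow(regs))) {
    inside <- ib$patient_id == regs$patient_id[i] &
      ib$date >= regs$start_date[i] & ib$date <= regs$coverage_end_date[i]
    expect_gte(sum(inside), 1)
  }
  expect_true(all(regs$n_dispensations >= 1))
})

test_that("the survival benchmark validates hazards and censors correctly", {
  expect_error(
    generate_survival_benchmark(10, baseline_hazard = c(
      event = 0, hospitalization = 0)),
    class = "cllclaims_config_error")

  # zero horizon: every record censored at 0; fitting finds no events
  b <- generate_survival_benchmark(20, censor_horizon = 0, seed = 4)
  expect_true(all(b$records$event == 0))
  expect_error(cox_fit(b$records, c("x1", "x2")),
               class = "cllclaims_fit_error")
})

test_that("with null effects the two groups are exchangeable", {
  # log-rank p-values over replicates stay roughly uniform
  set.seed(60)
  p <- vapply(1:40, function(r) {
    b <- generate_survival_benchmark(
      120, true_log_hr = c(x1 = 0, x2 = 0, hosp = 0), seed = 5000 + r)
    one <- b$records[b$records$hosp == 0 & b$records$entry == 0, ]
    f <- cox_fit(one, "x1")
    f$score_test$p
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})
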