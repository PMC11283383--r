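origin <- as.Date("2018-01-01")

test_that("refills within the grace period extend a single regimen", {
  r <- build_regimens(origin + c(0, 25), c(28L, 28L),
                      followup_end = origin + 400)
  expect_equal(nrow(r), 1L)
  expect_equal(as.numeric(r$start_date - origin), 0)
  expect_equal(as.numeric(r$coverage_end_date - origin), 52)
  expect_equal(r$n_dispensations, 2L)
})

test_that("a long break opens a second regimen", {
  r <- build_regimens(origin + c(0, 150), c(28L, 28L),
                      followup_end = origin + 400, grace_days = 30,
                      discontinuation_days = 90)
  expect_equal(nrow(r), 2L)
  expect_equal(as.numeric(r$coverage_end_date - origin), c(27, 177))
  # 122 uncovered days between the regimens
  expect_equal(as.numeric(r$start_date[2] - r$coverage_end_date[1]) - 1, 122)
  expect_true(r$completed[1])
  expect_equal(r$end_reason[1], "discontinuation")
})

test_that("coverage running past follow-up is right-censored", {
  r <- build_regimens(origin + c(0, 25), c(90L, 90L),
                      followup_end = origin + 60)
  expect_equal(nrow(r), 1L)
  expect_false(r$completed)
  expect_equal(r$end_reason, "end_of_followup")
  expect_equal(r$coverage_end_date, origin + 60)

  # a death during coverage closes the regimen as death
  r2 <- build_regimens(origin + c(0, 25), c(90L, 90L),
                       followup_end = origin + 60,
                       death_date = origin + 60)
  expect_equal(r2$end_reason, "death")
  expect_true(r2$completed)
})

test_that("dispensations after follow-up are ignored with a warning", {
  expect_warning(
    r <- build_regimens(origin + c(0, 500), c(28L, 28L),
                        followup_end = origin + 100),
    "after end of follow-up")
  expect_equal(r$n_dispensations, 1L)
})

test_that("regimen construction matches the day-by-day coverage oracle", {
  set.seed(101)
  for (i in 1:150) {
    h <- random_history()
    res <- run_both_regimen_builders(h)
    expect_equal(res$got, res$want, info = sprintf("history %d", i))
  }
})

test_that("raising the grace period never increases the regimen count", {
  set.seed(202)
  for (i in 1:50) {
    h <- random_history()
    n_reg <- vapply(c(0, 10, 20, 40, 80), function(g) {
      nrow(build_regimens(origin + h$days, h$quantities,
                          followup_end = origin + h$followup,
                          grace_days = g))
    }, numeric(1))
    expect_true(all(diff(n_reg) <= 0))
  }
})

test_that("line assignment keys on prior CLL-specific exposure", {
  idx <- as.Date("2018-01-01")
  disp <- data.frame(
    patient_id = "X",
    date = as.Date(c("2014-01-01", "2018-01-01")),
    atc_code = c("L01FA01", "L01EL01"),  # rituximab, then ibrutinib
    quantity = c(1L, 28L), stringsAsFactors = FALSE)
  line <- assign_line(idx, disp)
  expect_equal(line$line, "L2plus")
  expect_equal(line$years_since_first_treatment, 4.0, tolerance = 0.01)

  # a non-CLL drug does not create a prior line
  disp$atc_code[1] <- "L02BG04"  # letrozole
  expect_equal(assign_line(idx, disp)$line, "L1")
  expect_true(is.na(assign_line(idx, disp)$first_cll_treatment_date))
})

test_that("cotherapy is restricted to the regimen coverage interval", {
  reg <- data.frame(ordinal = 1L, start_date = origin,
                    coverage_end_date = origin + 100,
                    n_dispensations = 4L, completed = TRUE,
                    end_reason = "discontinuation", stringsAsFactors = FALSE)
  disp <- data.frame(
    patient_id = "X", date = origin + c(27, 110),
    atc_code = c("L01FA01", "L01FA01"), quantity = 1L,
    stringsAsFactors = FALSE)
  cot <- detect_cotherapy(reg, disp)
  expect_equal(nrow(cot), 1L)
  expect_equal(cot$co_drug, "rituximab")
  expect_equal(cot$days_from_regimen_start, 27)

  expect_equal(nrow(detect_cotherapy(reg, disp[0, ])), 0L)
})

test_that("next treatment is the earliest post-regimen candidate", {
  reg <- data.frame(ordinal = 1L, start_date = origin,
                    coverage_end_date = origin + 400,
                    n_dispensations = 10L, completed = TRUE,
                    end_reason = "discontinuation", stringsAsFactors = FALSE)
  disp <- data.frame(
    patient_id = "X", date = origin + c(100, 440, 440, 460),
    atc_code = c("L01FA01", "L01XX52", "L01EM01", "L01AA09"),
    quantity = 1L, stringsAsFactors = FALSE)
  nxt <- find_next_treatment(reg, disp, origin + 600)
  expect_equal(nxt$date, origin + 440)
  # same-day tie: one date, all labels alphabetically
  expect_equal(nxt$drugs, c("idelalisib", "venetoclax"))

  # a drug only during the regimen is cotherapy, not a next treatment
  nxt2 <- find_next_treatment(reg, disp[1, , drop = FALSE], origin + 600)
  expect_true(is.na(nxt2$date))
})

test_that("the treatment-free interval is nonnegative and boundary-safe", {
  expect_equal(compute_tfi(origin + 400, origin + 433), 33)
  expect_equal(compute_tfi(origin + 400, origin + 400), 0)
  expect_true(is.na(compute_tfi(origin + 400, as.Date(NA))))
  expect_error(compute_tfi(origin + 400, origin + 399),
               class = "cllclaims_consistency_error")
})
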