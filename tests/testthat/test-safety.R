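idx <- as.Date("2018-03-01")

regs1 <- data.frame(ordinal = 1L, start_date = idx,
                    coverage_end_date = idx + 300, n_dispensations = 10L,
                    completed = TRUE, end_reason = "discontinuation",
                    stringsAsFactors = FALSE)

mk_stay <- function(main, date, related = "", associated = "") {
  data.frame(patient_id = "X", admission_date = as.Date(date),
             discharge_date = as.Date(date) + 6, main_dx = main,
             related_dx = related, associated_dx = associated,
             device_codes = "", stringsAsFactors = FALSE)
}

test_that("event detection uses main/related diagnoses within exposure", {
  ev <- detect_event_hospitalizations(idx, regs1, mk_stay("I48.0", idx + 100))
  expect_equal(ev$category, "atrial_fibrillation")
  expect_equal(ev$duration_days, 6)
  expect_equal(ev$months_from_index, 100 / 30.4375)

  # a related diagnosis also counts
  ev <- detect_event_hospitalizations(idx, regs1,
                                      mk_stay("Z511", idx + 50, "K920"))
  expect_equal(ev$category, "bleeding")

  # an associated-position diagnosis does not
  ev <- detect_event_hospitalizations(
    idx, regs1, mk_stay("Z511", idx + 50, associated = "I48"))
  expect_equal(nrow(ev), 0L)

  # admissions after the coverage end are outside the exposure period
  ev <- detect_event_hospitalizations(idx, regs1, mk_stay("I48", idx + 350))
  expect_equal(nrow(ev), 0L)

  # one record per (stay, category) when codes span two categories
  ev <- detect_event_hospitalizations(idx, regs1,
                                      mk_stay("I48", idx + 10, "I50"))
  expect_equal(sort(ev$category),
               c("atrial_fibrillation", "heart_failure"))
})

test_that("event counts are invariant to stay ordering", {
  stays <- rbind(mk_stay("I48", idx + 10), mk_stay("I50", idx + 200),
                 mk_stay("K920", idx + 100))
  e1 <- detect_event_hospitalizations(idx, regs1, stays)
  e2 <- detect_event_hospitalizations(idx, regs1, stays[3:1, ])
  rownames(e1) <- rownames(e2) <- NULL
  expect_identical(e1, e2)
})

test_that("continuation after the first event hospitalization", {
  ev <- detect_event_hospitalizations(idx, regs1, mk_stay("I48", idx + 194))
  discharge <- idx + 200
  got <- continued_after_event(ev, c(idx, discharge + 18), idx + 400)
  expect_true(got$continued)
  expect_equal(got$delay_days, 18)

  got <- continued_after_event(ev, idx, idx + 400)  # nothing after discharge
  expect_false(got$continued)
  expect_true(is.na(got$delay_days))

  got <- continued_after_event(ev, discharge, idx + 400)  # same-day refill
  expect_true(got$continued)
  expect_equal(got$delay_days, 0)
})

test_that("medication initiation distinguishes new users and add-ons", {
  mk_disp <- function(atc, dates) {
    data.frame(patient_id = "X", date = as.Date(dates), atc_code = atc,
               quantity = 30L, stringsAsFactors = FALSE)
  }
  # no pre-index antihypertensive, one started at index + 90
  m <- medication_initiation(idx, mk_disp("C09AA05", idx + 90))
  expect_true(m$antihypertensive_initiation_or_addon)
  expect_true(m$any)

  # pre-index classes {C03, C07}; C08 added post-index -> third agent
  d <- rbind(mk_disp("C03CA01", idx - 200), mk_disp("C07AB02", idx - 150),
             mk_disp("C03CA01", idx + 30), mk_disp("C07AB02", idx + 40),
             mk_disp("C08CA01", idx + 60))
  m <- medication_initiation(idx, d)
  expect_true(m$antihypertensive_initiation_or_addon)

  # a prevalent warfarin user is not an initiator
  d <- rbind(mk_disp("B01AA03", idx - 100), mk_disp("B01AA03", idx + 100))
  m <- medication_initiation(idx, d)
  expect_false(m$anticoagulant_initiation)
  expect_false(m$any)

  # a new anticoagulant user is
  m <- medication_initiation(idx, mk_disp("B01AF01", idx + 100))
  expect_true(m$anticoagulant_initiation)
})
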