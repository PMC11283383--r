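test_that("cohort selection applies the inclusion cascade in order", {
  b <- make_mini_bundle()
  sel <- select_cohort(b)
  # A: first ibrutinib 2017-09-01, covered, later care -> included
  expect_true("A" %in% sel$members$patient_id)
  # C: not covered by the general scheme -> excluded at step 2
  expect_false("C" %in% sel$members$patient_id)
  expect_equal(sel$flowchart$steps$n_excluded[2], 1)
  # flowchart conserves counts at every step
  st <- sel$flowchart$steps
  expect_equal(st$n_before - st$n_excluded, st$n_after)
  expect_equal(st$n_before[-1], st$n_after[-nrow(st)])
})

test_that("initiation before the window and silent patients are excluded", {
  b <- make_mini_bundle()
  # give A a pre-window ibrutinib dispensation: no longer an initiator
  extra <- data.frame(patient_id = "A", date = as.Date("2017-07-15"),
                      atc_code = "L01EL01", quantity = 28L,
                      stringsAsFactors = FALSE)
  b2 <- claims_bundle(b$patients, rbind(b$dispensations, extra), b$stays,
                      b$ltd_statuses)
  sel <- select_cohort(b2)
  expect_false("A" %in% sel$members$patient_id)
  expect_equal(sel$flowchart$steps$n_excluded[1], 1)

  # a single dispensation, no later care, alive -> excluded
  pat <- data.frame(patient_id = "S", sex = "male",
                    birth_year_month = "1950-01",
                    death_date = as.Date(NA),
                    general_scheme_covered = TRUE, stringsAsFactors = FALSE)
  disp <- data.frame(patient_id = "S", date = as.Date("2018-06-01"),
                     atc_code = "L01EL01", quantity = 28L,
                     stringsAsFactors = FALSE)
  sel2 <- select_cohort(claims_bundle(pat, disp))
  expect_equal(nrow(sel2$members), 0L)
  expect_equal(sel2$flowchart$steps$n_excluded[3], 1)
})

test_that("follow-up ends at death, a six-month care gap, or study end", {
  idx <- as.Date("2018-01-01")
  se <- as.Date("2020-12-31")

  fu <- compute_followup(idx, as.Date("2019-05-01"),
                         seq(idx, se, by = 30), se)
  expect_equal(fu$reason, "death")
  expect_equal(fu$followup_end, as.Date("2019-05-01"))

  # 234-day gap -> lost to follow-up at the last care before the gap
  care <- c(seq(idx, as.Date("2019-01-10"), by = 30),
            as.Date(c("2019-01-10", "2019-09-01", "2019-10-01")))
  fu <- compute_followup(idx, as.Date(NA), care, se)
  expect_equal(fu$reason, "lost_to_followup")
  expect_equal(fu$followup_end, as.Date("2019-01-10"))

  fu <- compute_followup(idx, as.Date(NA), seq(idx, se, by = 28), se)
  expect_equal(fu$reason, "end_of_study")
  expect_equal(fu$followup_end, se)

  # death inside a qualifying care-free period takes precedence over the gap
  fu <- compute_followup(idx, as.Date("2019-03-01"),
                         seq(idx, as.Date("2019-01-10"), by = 30), se)
  expect_equal(fu$reason, "death")
  expect_equal(fu$followup_end, as.Date("2019-03-01"))
})

test_that("follow-up is monotone in the study end, up to gap disclosure", {
  # Extending the study end can only shorten follow-up in one situation:
  # a trailing care-free period too short to qualify under the earlier
  # study end becomes a fully observable six-month gap under the later
  # one, reclassifying the patient as lost to follow-up at their last
  # care record.  Otherwise follow-up is monotone.
  set.seed(42)
  idx <- as.Date("2018-01-01")
  for (r in 1:50) {
    care <- idx + sort(sample(0:1000, sample(2:12, 1)))
    death <- if (runif(1) < 0.3) idx + sample(100:900, 1) else as.Date(NA)
    e1 <- compute_followup(idx, death, care, as.Date("2019-12-31"))
    e2 <- compute_followup(idx, death, care, as.Date("2020-12-31"))
    ok <- as.numeric(e2$followup_end) >= as.numeric(e1$followup_end) ||
      (e1$reason == "end_of_study" && e2$reason == "lost_to_followup" &&
         e2$followup_end %in% care)
    expect_true(ok)
  }
})

test_that("indication classification follows the two-branch rule", {
  idx <- as.Date("2018-01-01")
  mk_ltd <- function(code, date) {
    data.frame(patient_id = "X", icd10_code = code,
               start_date = as.Date(date), stringsAsFactors = FALSE)
  }
  mk_stay <- function(code, date) {
    data.frame(patient_id = "X", admission_date = as.Date(date),
               discharge_date = as.Date(date) + 3, main_dx = code,
               related_dx = "", associated_dx = "", device_codes = "",
               stringsAsFactors = FALSE)
  }
  e_ltd <- mk_ltd("Z00", "2010-01-01")[0, ]
  e_stay <- mk_stay("Z00", "2010-01-01")[0, ]

  # the LAST pre-index diagnosis wins
  expect_equal(
    classify_indication(idx, idx + 300, mk_ltd("C911", "2015-03-01"),
                        mk_stay("C831", "2016-06-01")),
    "MCL")
  # no pre-index code: first diagnosis up to 30 d after last dispensation
  expect_equal(
    classify_indication(idx, idx + 300, e_ltd, mk_stay("C911", idx + 10)),
    "CLL")
  # only diagnosis 45 d after the last dispensation -> outside the window
  expect_equal(
    classify_indication(idx, idx + 100, e_ltd, mk_stay("C880", idx + 145)),
    "unclassified")
  # two different codes on the qualifying date -> restrictive tie rule
  two <- rbind(mk_ltd("C911", "2016-06-01"), mk_ltd("C831", "2016-06-01"))
  expect_equal(classify_indication(idx, idx + 300, two, e_stay),
               "unclassified")
  # dotted codes normalize to the same prefix
  expect_equal(
    classify_indication(idx, idx + 300, mk_ltd("C91.1", "2016-06-01"),
                        e_stay),
    "CLL")
})
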