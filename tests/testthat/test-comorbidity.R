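idx <- as.Date("2019-06-01")

mk_stay <- function(code, date, device = "") {
  data.frame(patient_id = "X", admission_date = as.Date(date),
             discharge_date = as.Date(date) + 4, main_dx = code,
             related_dx = "", associated_dx = "", device_codes = device,
             stringsAsFactors = FALSE)
}
e_stay <- mk_stay("Z00", idx)[0, ]
mk_ltd <- function(code, date) {
  data.frame(patient_id = "X", icd10_code = code,
             start_date = as.Date(date), stringsAsFactors = FALSE)
}
e_ltd <- mk_ltd("Z00", idx)[0, ]
e_disp <- data.frame(patient_id = character(0),
                     date = as.Date(character(0)),
                     atc_code = character(0), quantity = integer(0),
                     stringsAsFactors = FALSE)

test_that("the twelve-month lookback window gates hospital diagnoses", {
  p <- comorbidity_profile(idx, e_ltd, mk_stay("I50", idx - 100), e_disp,
                           age = 60)
  expect_true(p$cardiovascular.heart_failure_arrhythmia_valvular)
  expect_true(p$cardiovascular)

  p <- comorbidity_profile(idx, e_ltd, mk_stay("I50", idx - 400), e_disp,
                           age = 60)
  expect_false(p$cardiovascular)
  expect_equal(p$n_comorbidities, 0L)

  # an LTD is a standing status: it counts whenever active at index
  p <- comorbidity_profile(idx, mk_ltd("C50", idx - 900), e_stay, e_disp,
                           age = 60)
  expect_true(p$solid_tumour)
})

test_that("probabilistic markers flag cardiovascular disease without codes", {
  # three antiplatelet dispensations in the lookback, no diagnosis
  disp <- data.frame(patient_id = "X", date = idx - c(300, 200, 100),
                     atc_code = "B01AC06", quantity = 30L,
                     stringsAsFactors = FALSE)
  p <- comorbidity_profile(idx, e_ltd, e_stay, disp, age = 60)
  expect_true(p$cv_marker_only)
  expect_true(p$cardiovascular)

  # one isolated anticoagulant is below the chronic-use threshold
  m <- cardiovascular_markers(idx, e_stay, disp[1, , drop = FALSE])
  expect_false(m$marker)

  # a pacemaker device code on any pre-index stay
  m <- cardiovascular_markers(idx, mk_stay("Z95", idx - 200, "PACEMAKER"),
                              e_disp)
  expect_true(m$pacemaker)

  # a marker alongside a CV diagnosis is not marker-only
  p <- comorbidity_profile(idx, mk_ltd("I50", idx - 500),
                           e_stay, disp, age = 60)
  expect_true(p$cardiovascular)
  expect_false(p$cv_marker_only)
})

test_that("the Charlson index applies Quan weights, hierarchy and age points", {
  # leukaemia alone at age 75: malignancy 2 + age 3
  expect_equal(charlson_index("C911", 75), 5L)
  # no diagnoses, below the first age band
  expect_equal(charlson_index(character(0), 45), 0L)
  # metastatic disease supersedes the primary malignancy: 6, not 6 + 2
  expect_equal(charlson_index(c("C78", "C50"), 45), 6L)
  # complicated diabetes supersedes uncomplicated
  expect_equal(charlson_index(c("E112", "E119"), 45), 2L)
  # age bands: +1 per decade from 50-59, capped at +4
  expect_equal(charlson_index(character(0), 55), 1L)
  expect_equal(charlson_index(character(0), 92), 4L)
  expect_equal(charlson_index("C911", 75, age_points = FALSE), 2L)
})

test_that("adding a diagnosis never lowers the Charlson score", {
  set.seed(7)
  pool <- c("I21", "I50", "I70", "G45", "F03", "J44", "M05", "K25",
            "B18", "E119", "E112", "G81", "N18", "C911", "C50", "C78",
            "K721", "B20", "Z000")
  for (r in 1:40) {
    base <- sample(pool, sample(0:5, 1))
    extra <- sample(pool, 1)
    expect_gte(charlson_index(c(base, extra), 70),
               charlson_index(base, 70))
  }
})

test_that("profiles are independent of record ordering", {
  stays <- rbind(mk_stay("I50", idx - 100), mk_stay("C50", idx - 50),
                 mk_stay("J96", idx - 200))
  disp <- data.frame(patient_id = "X", date = idx - c(300, 200, 100),
                     atc_code = "B01AA03", quantity = 30L,
                     stringsAsFactors = FALSE)
  p1 <- comorbidity_profile(idx, e_ltd, stays, disp, age = 71)
  p2 <- comorbidity_profile(idx, e_ltd, stays[3:1, ], disp[3:1, ], age = 71)
  expect_identical(p1, p2)
  expect_equal(p1$n_comorbidities, 3L)
})
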