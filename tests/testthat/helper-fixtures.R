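# Shared fixtures and independent oracles, built in code at test time.

# A small, fully hand-checkable three-patient bundle.
make_mini_bundle <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    sex = c("male", "female", "male"),
    birth_year_month = c("1945-03", "1952-11", "1938-07"),
    death_date = as.Date(c(NA, "2019-05-01", NA)),
    general_scheme_covered = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  dispensations <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C"),
    date = as.Date(c("2017-09-01", "2017-09-29", "2018-01-10",
                     "2018-03-05", "2018-04-02", "2019-02-01")),
    atc_code = c("L01EL01", "L01EL01", "L01XX52",
                 "L01EL01", "L01EL01", "L01EL01"),
    quantity = c(28L, 28L, 30L, 28L, 28L, 28L),
    stringsAsFactors = FALSE
  )
  stays <- data.frame(
    patient_id = c("A", "B"),
    admission_date = as.Date(c("2016-06-01", "2018-01-20")),
    discharge_date = as.Date(c("2016-06-05", "2018-01-25")),
    main_dx = c("C911", "C831"),
    related_dx = c("I10", ""),
    associated_dx = c("", "E119"),
    device_codes = c("", ""),
    stringsAsFactors = FALSE
  )
  ltd <- data.frame(
    patient_id = "A",
    icd10_code = "C911",
    start_date = as.Date("2015-03-01"),
    stringsAsFactors = FALSE
  )
  claims_bundle(patients, dispensations, stays, ltd)
}

# Independent day-by-day regimen oracle: mark every covered calendar day,
# extract maximal covered runs, then merge runs separated by at most
# grace_days uncovered days.  Completely separate from the incremental
# grouping in build_regimens.
oracle_regimens <- function(days, quantities, grace_days, followup_day) {
  keep <- days <= followup_day
  days <- days[keep]; quantities <- quantities[keep]
  if (length(days) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_disp = integer(0)))
  }
  covered <- sort(unique(unlist(mapply(
    function(d, q) seq(d, d + q - 1), days, quantities,
    SIMPLIFY = FALSE))))
  run_break <- which(diff(covered) > 1)
  run_start <- covered[c(1, run_break + 1)]
  run_end <- covered[c(run_break, length(covered))]
  # merge runs whose uncovered gap is at most grace_days
  groups <- cumsum(c(1, (run_start[-1] - run_end[-length(run_end)] - 1) >
                       grace_days))
  start <- tapply(run_start, groups, min)
  end <- tapply(run_end, groups, max)
  # a regimen starts at a dispensation date, not merely a covered day
  start_disp <- vapply(seq_along(start), function(g) {
    min(days[days >= start[g] & days <= end[g]])
  }, numeric(1))
  n_disp <- vapply(seq_along(start), function(g) {
    sum(days >= start[g] & days <= end[g])
  }, integer(1))
  data.frame(start = start_disp, end = pmin(unname(end), followup_day),
             n_disp = n_disp, row.names = NULL)
}

# Random dispensation histories for the oracle-equivalence checks.
random_history <- function() {
  n <- sample(1:8, 1)
  days <- sort(sample(0:400, n))
  quantities <- sample(1:60, n, replace = TRUE)
  grace <- sample(0:45, 1)
  followup <- max(days) + sample(0:100, 1)
  list(days = days, quantities = quantities, grace = grace,
       followup = followup)
}

run_both_regimen_builders <- function(h) {
  origin <- as.Date("2018-01-01")
  got <- build_regimens(origin + h$days, h$quantities,
                        followup_end = origin + h$followup,
                        grace_days = h$grace)
  want <- oracle_regimens(h$days, h$quantities, h$grace, h$followup)
  list(
    got = data.frame(start = as.numeric(got$start_date - origin),
                     end = as.numeric(got$coverage_end_date - origin),
                     n_disp = got$n_dispensations),
    want = data.frame(start = want$start, end = want$end,
                      n_disp = as.integer(want$n_disp))
  )
}
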