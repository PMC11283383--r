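# Pipeline orchestration: run every stage on a claims bundle and emit a
# study report shaped like the standard deliverables of a claims-based
# drug-utilisation study -- flowchart, baseline table, treatment-pattern
# tables, safety table, Cox table, and Kaplan-Meier curves overall and by
# cardiovascular comorbidity.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated
#' object.
#'
#' @param ibrutinib_atc ATC code(s) identifying ibrutinib.
#' @param gap_days loss-to-follow-up care gap (days).
#' @param grace_days regimen grace period (days).
#' @param discontinuation_days permanent-discontinuation threshold (days).
#' @param post_window_days indication tail window (days).
#' @param marker_k antithrombotic marker dispensing threshold.
#' @param age_points include Charlson age points.
#' @param codes a [default_drug_codes()] list.
#' @param codemap a [load_codemap()] list.
#' @return list, class `"pipeline_config"`.
#' @export
pipeline_config <- function(ibrutinib_atc = "L01EL01", gap_days = 183L,
                            grace_days = 30L, discontinuation_days = 90L,
                            post_window_days = 30L, marker_k = 3L,
                            age_points = TRUE,
                            codes = default_drug_codes(),
                            codemap = load_codemap()) {
  if (length(ibrutinib_atc) == 0L || !any(nzchar(ibrutinib_atc))) {
    claims_abort("ibrutinib ATC code list must not be empty",
                 "cllclaims_config_error")
  }
  thresholds <- c(gap_days, grace_days, discontinuation_days,
                  post_window_days, marker_k)
  if (any(thresholds <= 0)) {
    claims_abort("thresholds must be positive", "cllclaims_config_error")
  }
  structure(as.list(environment())[c(
    "ibrutinib_atc", "gap_days", "grace_days", "discontinuation_days",
    "post_window_days", "marker_k", "age_points", "codes", "codemap"
  )], class = "pipeline_config")
}

count_pct <- function(k, n) {
  list(n = as.integer(k), pct = if (n > 0) 100 * k / n else NA_real_)
}

#' Run the full analysis pipeline on a claims bundle
#'
#' Stages: cohort selection and indication phenotyping; regimen, line,
#' cotherapy and next-treatment construction; comorbidity profiling;
#' safety-event detection and medication initiation; endpoint construction
#' (TTNT, TTD) and estimation (Kaplan-Meier, Cox with the time-dependent
#' hospitalization covariate).  Downstream analysis is restricted to the
#' CLL indication.  The run is deterministic given the bundle and
#' configuration.
#'
#' @param bundle a validated [claims_bundle()].
#' @param config a [pipeline_config()].
#' @return object of class `"study_report"`: `flowchart`, per-table blocks
#'   (`table1` .. `table5`), `km`, and the per-patient `analysis` frame.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!inherits(config, "pipeline_config")) {
    claims_abort("config must be a pipeline_config", "cllclaims_config_error")
  }
  codes <- config$codes
  codemap <- config$codemap

  message("stage cohort: selecting ibrutinib initiators")
  sel <- select_cohort(bundle, ibrutinib_atc = config$ibrutinib_atc,
                       gap_days = config$gap_days,
                       post_window_days = config$post_window_days)
  members <- sel$members
  cll <- members[members$indication == "CLL", , drop = FALSE]
  message(sprintf("stage cohort: %d included, %d CLL", nrow(members),
                  nrow(cll)))

  pat <- bundle$patients
  disp_by <- split(bundle$dispensations, bundle$dispensations$patient_id)
  stays_by <- split(bundle$stays, bundle$stays$patient_id)
  ltd_by <- split(bundle$ltd_statuses, bundle$ltd_statuses$patient_id)
  e_disp <- empty_dispensations(); e_stay <- empty_stays(); e_ltd <- empty_ltd()

  message("stage exposure/comorbidity/safety: profiling patients")
  rows <- vector("list", nrow(cll))
  regimen_list <- vector("list", nrow(cll))
  for (i in seq_len(nrow(cll))) {
    id <- cll$patient_id[i]
    idx <- cll$index_date[i]
    fend <- cll$followup_end[i]
    pd <- disp_by[[id]] %||% e_disp
    ps <- stays_by[[id]] %||% e_stay
    pl <- ltd_by[[id]] %||% e_ltd
    prow <- pat[match(id, pat$patient_id), ]
    death <- prow$death_date

    ib <- pd[pd$atc_code %in% config$ibrutinib_atc, , drop = FALSE]
    regs <- build_regimens(ib$date, ib$quantity, followup_end = fend,
                           death_date = death,
                           grace_days = config$grace_days,
                           discontinuation_days = config$discontinuation_days)
    regimen_list[[i]] <- cbind(patient_id = id, regs)
    last <- regs[nrow(regs), , drop = FALSE]

    line <- assign_line(idx, pd, codes = codes)
    cot <- detect_cotherapy(regs[1, , drop = FALSE], pd, codes = codes)
    nxt <- find_next_treatment(regs, pd, fend, codes = codes)
    tfi <- if (!is.na(nxt$date)) {
      compute_tfi(last$coverage_end_date, nxt$date)
    } else NA_real_

    age <- age_at_date(prow$birth_year_month, idx)
    prof <- comorbidity_profile(idx, pl, ps, pd, age, codemap = codemap,
                                codes = codes, marker_k = config$marker_k,
                                age_points = config$age_points)

    ev <- detect_event_hospitalizations(idx, regs, ps, codemap = codemap)
    cont <- if (nrow(ev)) continued_after_event(ev, ib$date, fend) else
      list(continued = NA, delay_days = NA_real_)
    med <- medication_initiation(idx, pd, codes = codes)

    disc_date <- if (last$end_reason == "discontinuation") {
      last$coverage_end_date
    } else as.Date(NA_character_)
    ttnt <- compute_ttnt(idx, nxt$date, death, fend)
    ttd <- compute_ttd(idx, disc_date, death, fend)

    exposure_days <- as.numeric(last$coverage_end_date - idx)
    exposure_end_reason <- switch(
      last$end_reason,
      death = "death",
      discontinuation = "discontinuation",
      end_of_followup = if (cll$followup_reason[i] == "lost_to_followup")
        "lost_to_followup" else "end_of_study"
    )
    first_hosp <- if (nrow(ev)) {
      as.numeric(min(ev$admission_date) - idx)
    } else NA_real_
    first_hosp_dur <- if (nrow(ev)) {
      ev$duration_days[which.min(ev$admission_date)]
    } else NA_real_

    # last CLL-specific treatment before index (treatment history)
    prior <- pd[pd$atc_code %in% codes$cll_specific & pd$date < idx, ,
                drop = FALSE]
    last_prior_date <- if (nrow(prior)) max(prior$date) else
      as.Date(NA_character_)
    last_prior_drug <- if (nrow(prior)) {
      sort(drug_label(prior$atc_code[prior$date == last_prior_date],
                      codes))[1]
    } else NA_character_

    rows[[i]] <- data.frame(
      patient_id = id, index_date = idx, followup_end = fend,
      followup_reason = cll$followup_reason[i],
      followup_days = as.numeric(fend - idx),
      age = age, sex = prow$sex, female = as.integer(prow$sex == "female"),
      death = as.integer(!is.na(death) & death <= fend),
      n_regimens = nrow(regs),
      first_reg_start = regs$start_date[1],
      first_reg_end = regs$coverage_end_date[1],
      first_reg_n_disp = regs$n_dispensations[1],
      first_reg_completed = regs$completed[1],
      first_reg_length = as.numeric(regs$coverage_end_date[1] -
                                      regs$start_date[1]),
      inter_regimen_break = if (nrow(regs) >= 2) {
        # uncovered days between the first two regimens
        as.numeric(regs$start_date[2] - regs$coverage_end_date[1]) - 1
      } else NA_real_,
      cotherapy = as.integer(nrow(cot) > 0),
      cotherapy_days = if (nrow(cot)) cot$days_from_regimen_start[1]
        else NA_real_,
      line = line$line,
      l2plus = as.integer(line$line == "L2plus"),
      years_since_first_treatment = line$years_since_first_treatment,
      last_prior_drug = last_prior_drug,
      time_since_prior_days = if (!is.na(last_prior_date))
        as.numeric(idx - last_prior_date) else NA_real_,
      next_treatment = as.integer(!is.na(nxt$date)),
      next_drugs = paste(nxt$drugs, collapse = "+"),
      tfi_days = tfi,
      exposure_days = exposure_days,
      exposure_end_reason = exposure_end_reason,
      cardiovascular = as.integer(prof$cardiovascular),
      cv_marker_only = as.integer(prof$cv_marker_only),
      n_comorbidities = prof$n_comorbidities,
      charlson = prof$charlson,
      liver = as.integer(prof$liver_cirrhosis),
      respiratory = as.integer(prof$respiratory_failure),
      kidney = as.integer(prof$kidney_disease),
      solid_tumour = as.integer(prof$solid_tumour),
      cv_stroke = as.integer(prof$cardiovascular.disabling_stroke),
      cv_arterial = as.integer(prof$cardiovascular.chronic_arterial_disease),
      cv_hf = as.integer(prof$cardiovascular.heart_failure_arrhythmia_valvular),
      cv_htn = as.integer(prof$cardiovascular.severe_hypertension),
      cv_coronary = as.integer(prof$cardiovascular.coronary_artery_disease),
      n_event_hosp = length(unique(ev$admission_date)),
      event_categories = paste(sort(unique(ev$category)), collapse = "+"),
      first_hosp_days = first_hosp,
      first_hosp_duration = first_hosp_dur,
      continued_after_hosp = if (is.na(cont$continued)) NA_integer_
        else as.integer(cont$continued),
      continued_delay = cont$delay_days,
      med_aht = prof_flag(med$antihypertensive_initiation_or_addon),
      med_ac = prof_flag(med$anticoagulant_initiation),
      med_ap = prof_flag(med$antiplatelet_initiation),
      med_any = prof_flag(med$any),
      ttnt_time = ttnt$time, ttnt_event = ttnt$event,
      ttd_time = ttd$time, ttd_event = ttd$event,
      stringsAsFactors = FALSE
    )
  }
  analysis <- if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else data.frame()
  regimens <- if (length(regimen_list)) {
    out <- do.call(rbind, regimen_list); rownames(out) <- NULL; out
  } else data.frame()

  message("stage survival: estimating KM and Cox models")
  km <- km_block(analysis)
  table5 <- cox_block(analysis)

  report <- structure(
    list(
      flowchart = sel$flowchart,
      n_included = nrow(members),
      n_cll = nrow(cll),
      table1 = table1_block(analysis),
      table2 = table2_block(analysis),
      table3 = table3_block(analysis),
      table4 = table4_block(analysis),
      table5 = table5,
      km = km,
      analysis = analysis,
      regimens = regimens
    ),
    class = "study_report"
  )
  check_report_consistency(report)
  report
}

prof_flag <- function(x) as.integer(isTRUE(x))

months_block <- function(days) summary_block(days_to_months(days))

table1_block <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(list(n = 0L))
  age_breaks <- c(-Inf, 39, 49, 59, 69, 79, 89, Inf)
  age_labels <- c("<40", "40-49", "50-59", "60-69", "70-79", "80-89", ">=90")
  age_classes <- table(cut(a$age, age_breaks, labels = age_labels))
  charlson_classes <- c(
    "0" = sum(a$charlson == 0),
    "1-2" = sum(a$charlson %in% 1:2),
    "3-4" = sum(a$charlson %in% 3:4),
    ">=5" = sum(a$charlson >= 5)
  )
  list(
    n = n,
    followup_months = months_block(a$followup_days),
    followup_reason = as.list(table(factor(
      a$followup_reason,
      levels = c("end_of_study", "death", "lost_to_followup")))),
    male = count_pct(sum(a$sex == "male"), n),
    age = summary_block(a$age),
    age_classes = as.list(age_classes),
    deaths = count_pct(sum(a$death), n),
    n_comorbidities = as.list(table(factor(
      pmin(a$n_comorbidities, 4), levels = 0:4))),
    comorbidities = list(
      liver_cirrhosis = count_pct(sum(a$liver), n),
      cardiovascular = count_pct(sum(a$cardiovascular), n),
      cv_disabling_stroke = count_pct(sum(a$cv_stroke), n),
      cv_chronic_arterial = count_pct(sum(a$cv_arterial), n),
      cv_heart_failure_arrhythmia = count_pct(sum(a$cv_hf), n),
      cv_severe_hypertension = count_pct(sum(a$cv_htn), n),
      cv_coronary = count_pct(sum(a$cv_coronary), n),
      cv_marker_only = count_pct(sum(a$cv_marker_only), n),
      respiratory_failure = count_pct(sum(a$respiratory), n),
      kidney_disease = count_pct(sum(a$kidney), n),
      solid_tumour = count_pct(sum(a$solid_tumour), n)
    ),
    charlson_classes = as.list(charlson_classes)
  )
}

table2_block <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(list(n = 0L))
  l1 <- a$line == "L1"; l2 <- a$line == "L2plus"
  completed1 <- a$first_reg_completed
  list(
    n = n,
    L1 = count_pct(sum(l1), n),
    L1_monotherapy = count_pct(sum(l1 & a$cotherapy == 0), sum(l1)),
    L1_cotherapy = count_pct(sum(l1 & a$cotherapy == 1), sum(l1)),
    L2plus = count_pct(sum(l2), n),
    L2plus_monotherapy = count_pct(sum(l2 & a$cotherapy == 0), sum(l2)),
    L2plus_cotherapy = count_pct(sum(l2 & a$cotherapy == 1), sum(l2)),
    years_since_first_treatment =
      summary_block(a$years_since_first_treatment[l2]),
    completed_first_regimen = count_pct(sum(completed1), n),
    n_dispensations_completed_first =
      summary_block(a$first_reg_n_disp[completed1]),
    length_completed_first_days =
      summary_block(a$first_reg_length[completed1]),
    time_to_cotherapy_days =
      summary_block(a$cotherapy_days[a$cotherapy == 1]),
    second_regimen = count_pct(sum(a$n_regimens >= 2), n),
    inter_regimen_break_days = summary_block(a$inter_regimen_break)
  )
}

table3_block <- function(a) {
  comp <- a[a$first_reg_completed %in% TRUE, , drop = FALSE]
  n <- nrow(comp)
  if (n == 0L) return(list(n = 0L))
  prior <- !is.na(comp$time_since_prior_days)
  # next treatments: patients alive at end of study with permanent
  # discontinuation
  disc_alive <- comp$exposure_end_reason == "discontinuation" &
    comp$death == 0
  with_next <- disc_alive & comp$next_treatment == 1
  next_counts <- table(comp$next_drugs[with_next])
  prior_counts <- table(comp$last_prior_drug[prior])
  list(
    n = n,
    prior_treatment = count_pct(sum(prior), n),
    time_since_prior_days = summary_block(comp$time_since_prior_days[prior]),
    last_prior_drug = as.list(prior_counts),
    discontinued_alive = count_pct(sum(disc_alive), n),
    received_next = count_pct(sum(with_next), max(1L, sum(disc_alive))),
    tfi_months = months_block(comp$tfi_days[with_next]),
    next_drug = as.list(next_counts)
  )
}

table4_block <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(list(n = 0L))
  has_ev <- a$n_event_hosp > 0
  cat_count <- function(cat) {
    count_pct(sum(has_ev & grepl(cat, a$event_categories, fixed = TRUE)), n)
  }
  hosp_hist <- c("0" = sum(a$n_event_hosp == 0),
                 "1" = sum(a$n_event_hosp == 1),
                 "2" = sum(a$n_event_hosp == 2),
                 ">=3" = sum(a$n_event_hosp >= 3))
  cont <- a$continued_after_hosp
  list(
    n = n,
    exposure_months = months_block(a$exposure_days),
    exposure_end_reason = as.list(table(factor(
      a$exposure_end_reason,
      levels = c("end_of_study", "discontinuation", "death",
                 "lost_to_followup")))),
    any_event_hosp = count_pct(sum(has_ev), n),
    events = list(
      bleeding = cat_count("bleeding"),
      atrial_fibrillation = cat_count("atrial_fibrillation"),
      heart_failure = cat_count("heart_failure"),
      hypertension = cat_count("hypertension"),
      cardiac_arrest = cat_count("cardiac_arrest"),
      paroxysmal_tachycardia = cat_count("paroxysmal_tachycardia")
    ),
    hosp_histogram = as.list(hosp_hist),
    time_to_first_hosp_months = months_block(a$first_hosp_days),
    first_hosp_duration_days = summary_block(a$first_hosp_duration),
    continued_after_hosp = count_pct(sum(cont %in% 1L), max(1L, sum(has_ev))),
    continuation_delay_days = summary_block(a$continued_delay),
    med_initiation = list(
      any = count_pct(sum(a$med_any), n),
      antihypertensive = count_pct(sum(a$med_aht), n),
      anticoagulant = count_pct(sum(a$med_ac), n),
      antiplatelet = count_pct(sum(a$med_ap), n)
    )
  )
}

# Cox covariate design: the age classes <65 (reference), 65-69, >=70.
cox_data <- function(a) {
  endpoints <- data.frame(
    id = a$patient_id, time = a$ttnt_time, event = a$ttnt_event,
    female = a$female,
    age65_69 = as.integer(a$age >= 65 & a$age < 70),
    age70 = as.integer(a$age >= 70),
    cv = a$cardiovascular, l2plus = a$l2plus, med_init = a$med_any,
    stringsAsFactors = FALSE
  )
  to_counting_process(endpoints, a$first_hosp_days)
}

fit_or_na <- function(data, covars, label) {
  tryCatch({
    fit <- cox_fit(data, covars)
    co <- fit$coefficients
    co$model <- label
    co
  }, error = function(e) {
    data.frame(term = covars, estimate = NA_real_, se = NA_real_,
               hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p = NA_real_, model = label, stringsAsFactors = FALSE)
  })
}

cox_block <- function(a) {
  if (nrow(a) == 0L || sum(a$ttnt_event) == 0L) return(list())
  cp <- cox_data(a)
  groups <- list(female = "female", age = c("age65_69", "age70"),
                 cv = "cv", hosp = "hosp_event", l2plus = "l2plus",
                 med_init = "med_init")
  unadj <- do.call(rbind, lapply(names(groups), function(g) {
    fit_or_na(cp, groups[[g]], "unadjusted")
  }))
  all_covars <- unlist(groups, use.names = FALSE)
  adj <- fit_or_na(cp, all_covars, "adjusted")
  out <- rbind(unadj, adj)
  rownames(out) <- NULL
  out
}

km_summary <- function(time, event, at_months = c(12, 24, 36)) {
  km <- kaplan_meier(time, event)
  at_days <- at_months * DAYS_PER_MONTH
  s <- km_prob(km, at_days)
  list(
    n = km$n, n_events = km$n_events,
    median_months = if (is.na(km$median)) NA_real_ else
      days_to_months(km$median),
    event_prob = stats::setNames(as.list(1 - s), paste0("m", at_months)),
    curve = km$curve
  )
}

km_block <- function(a) {
  if (nrow(a) == 0L) return(list())
  at_months <- c(12, 24, 36)
  at_days <- at_months * DAYS_PER_MONTH
  death_time <- ifelse(a$death == 1, a$ttnt_time, a$followup_days)
  death_km <- kaplan_meier(pmax(death_time, 0.5), a$death)
  naive_death <- vapply(at_days, function(t) {
    mean(a$death == 1 & death_time <= t)
  }, numeric(1))
  cvp <- a$cardiovascular == 1
  list(
    ttnt = km_summary(a$ttnt_time, a$ttnt_event),
    ttd = km_summary(a$ttd_time, a$ttd_event),
    ttnt_cv_present = if (any(cvp))
      km_summary(a$ttnt_time[cvp], a$ttnt_event[cvp]) else NULL,
    ttnt_cv_absent = if (any(!cvp))
      km_summary(a$ttnt_time[!cvp], a$ttnt_event[!cvp]) else NULL,
    death_share = list(
      naive_proportion = stats::setNames(as.list(naive_death),
                                         paste0("m", at_months)),
      km_all_cause = stats::setNames(
        as.list(1 - km_prob(death_km, at_days)), paste0("m", at_months))
    )
  )
}

check_report_consistency <- function(report) {
  fc <- report$flowchart
  with_steps <- fc$steps
  if (nrow(with_steps) &&
      !all(with_steps$n_before - with_steps$n_excluded ==
             with_steps$n_after)) {
    claims_abort("flowchart tally does not conserve counts",
                 "cllclaims_consistency_error")
  }
  if (sum(fc$indication_counts) != fc$n_included) {
    claims_abort("indication counts do not sum to included patients",
                 "cllclaims_consistency_error")
  }
  a <- report$analysis
  if (nrow(a)) {
    t2 <- report$table2
    if (t2$L1$n + t2$L2plus$n != nrow(a)) {
      claims_abort("line counts do not sum to cohort size",
                   "cllclaims_consistency_error")
    }
    t4 <- report$table4
    if (sum(unlist(t4$hosp_histogram)) != nrow(a)) {
      claims_abort("hospitalization histogram does not sum to cohort size",
                   "cllclaims_consistency_error")
    }
  }
  invisible(report)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  included: %d (CLL: %d)\n", x$n_included, x$n_cll))
  if (length(x$km)) {
    cat(sprintf("  TTNT median: %s months; event prob 12/24/36 m: %s\n",
                if (is.na(x$km$ttnt$median_months)) "not reached" else
                  sprintf("%.1f", x$km$ttnt$median_months),
                paste(sprintf("%.0f%%", 100 * unlist(x$km$ttnt$event_prob)),
                      collapse = "/")))
  }
  invisible(x)
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
    if (is.data.frame(x)) {
      x[] <- lapply(x, strip)
      return(x)
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  fc <- report$flowchart
  strip(list(
    flowchart = list(steps = fc$steps,
                     indication_counts = as.list(fc$indication_counts),
                     n_included = fc$n_included),
    n_cll = report$n_cll,
    table1 = report$table1,
    table2 = report$table2,
    table3 = report$table3,
    table4 = report$table4,
    table5 = report$table5,
    km = lapply(report$km, function(b) {
      if (is.list(b) && !is.null(b$curve)) b[setdiff(names(b), "curve")]
      else b
    })
  ))
}

#' Render a study report to files
#'
#' Writes `report.json` (all table blocks), `cox_fit.json` (the Cox table
#' alone), per-curve Kaplan-Meier CSVs, and optionally a markdown summary
#' mirroring the tables' layout.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @param format subset of `c("json", "markdown")`.
#' @return invisible character vector of the files written.
#' @export
render_report <- function(report, dir, format = c("json", "markdown")) {
  stopifnot(inherits(report, "study_report"))
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  check_report_consistency(report)
  written <- character(0)

  if ("json" %in% format) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    written <- c(written, path)
    path <- file.path(dir, "cox_fit.json")
    jsonlite::write_json(report$table5, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    written <- c(written, path)
  }
  for (nm in c("ttnt", "ttd", "ttnt_cv_present", "ttnt_cv_absent")) {
    b <- report$km[[nm]]
    if (is.null(b)) {
      warning(sprintf("KM stratum '%s' is empty; no curve written", nm))
      next
    }
    path <- file.path(dir, sprintf("km_%s.csv", nm))
    utils::write.csv(b$curve, path, row.names = FALSE)
    written <- c(written, path)
  }
  if ("markdown" %in% format) {
    path <- file.path(dir, "report.md")
    writeLines(report_markdown(report), path)
    written <- c(written, path)
  }
  invisible(written)
}

report_markdown <- function(report) {
  lines <- c("# Study report", "",
             sprintf("Included initiators: %d; CLL cohort: %d",
                     report$n_included, report$n_cll), "",
             "## Flowchart", "",
             "| step | before | excluded | after |",
             "| --- | ---: | ---: | ---: |")
  st <- report$flowchart$steps
  for (i in seq_len(nrow(st))) {
    lines <- c(lines, sprintf("| %s | %d | %d | %d |", st$step[i],
                              st$n_before[i], st$n_excluded[i],
                              st$n_after[i]))
  }
  fmt_cp <- function(x) sprintf("%d (%.1f%%)", x$n, x$pct)
  if (report$n_cll > 0) {
    t1 <- report$table1
    lines <- c(lines, "", "## Baseline", "",
               sprintf("- Male: %s", fmt_cp(t1$male)),
               sprintf("- Age: mean %.1f (SD %.1f), median %.0f",
                       t1$age$mean, t1$age$sd, t1$age$median),
               sprintf("- Cardiovascular comorbidity: %s",
                       fmt_cp(t1$comorbidities$cardiovascular)),
               sprintf("- Charlson >= 5: %d", t1$charlson_classes$`>=5`))
    t2 <- report$table2
    lines <- c(lines, "", "## Treatment pattern", "",
               sprintf("- L1: %s; L2+: %s", fmt_cp(t2$L1), fmt_cp(t2$L2plus)),
               sprintf("- Completed first regimen: %s",
                       fmt_cp(t2$completed_first_regimen)))
    if (length(report$km)) {
      km <- report$km
      lines <- c(lines, "", "## Effectiveness", "",
                 sprintf("- TTNT event probability at 12/24/36 months: %s",
                         paste(sprintf("%.0f%%",
                                       100 * unlist(km$ttnt$event_prob)),
                               collapse = " / ")),
                 sprintf("- Median TTNT: %s",
                         if (is.na(km$ttnt$median_months)) "not reached"
                         else sprintf("%.1f months", km$ttnt$median_months)))
    }
    if (length(report$table5)) {
      lines <- c(lines, "", "## Cox model (TTNT)", "",
                 "| model | term | HR | 95% CI | p |",
                 "| --- | --- | ---: | --- | ---: |")
      t5 <- report$table5
      for (i in seq_len(nrow(t5))) {
        lines <- c(lines, sprintf(
          "| %s | %s | %.2f | [%.2f-%.2f] | %.4f |", t5$model[i],
          t5$term[i], t5$hr[i], t5$ci_low[i], t5$ci_high[i], t5$p[i]))
      }
    }
  }
  lines
}
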