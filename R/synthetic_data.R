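# Synthetic claims generator: produces claims bundles with planted ground
# truth so every downstream stage is testable without access-restricted
# data.  The generator emulates the structure of national-claims extracts
# for a mixed CLL/MCL/WM population of ibrutinib initiators: demographics,
# planted indication diagnoses, comorbidity diagnoses and probabilistic
# markers, monthly ibrutinib refills with optional regimen breaks,
# next-treatment / death / hospitalization event times driven by known
# log-hazard ratios, and routine care records that determine follow-up.

#' Configuration for the synthetic claims generator
#'
#' Defaults reflect the profile of an elderly, mostly male, heavily
#' pretreated real-world ibrutinib population: mean age 73 (SD 10), 61%
#' male, 46.6% with a cardiovascular comorbidity, 80% initiating in second
#' or later line, 28-capsule boxes refilled on a roughly monthly cadence.
#' Event hazards are per-day baselines; log-hazard ratios act on the
#' next-treatment and death hazards (covariates: age >= 70, cardiovascular
#' comorbidity, L2+, and a time-dependent hospitalization switch).
#'
#' @param n_patients number of patients (>= 0).
#' @param seed integer seed; every per-patient quantity derives from it.
#' @param disease_mix named probabilities over CLL, MCL, WM, other; must
#'   sum to 1.
#' @param age_mean,age_sd age distribution at index (years).
#' @param male_fraction probability of male sex.
#' @param cv_comorbidity_prevalence probability of a cardiovascular
#'   comorbidity at index.
#' @param cv_marker_only_fraction among cardiovascular patients, fraction
#'   carried only by a probabilistic marker (antithrombotic dispensing),
#'   without a diagnosis code.
#' @param prior_treatment_probability probability of a prior CLL-specific
#'   treatment (drives L2+).
#' @param dispensation_quantity capsules per box.
#' @param dispensation_interval_mean,dispensation_interval_sd refill
#'   cadence (days); draws are clipped to [21, 45] so that refill jitter
#'   never opens a regimen break.
#' @param regimen_break_probability probability of one deliberate break
#'   (second regimen) when the treatment window allows it.
#' @param regimen_break_mean,regimen_break_sd break length (days), clipped
#'   to [95, 160] so a break always exceeds both the grace period and the
#'   permanent-discontinuation threshold.
#' @param discontinuation_rate per-day hazard of spontaneous treatment stop.
#' @param lost_to_followup_probability probability that all care stops
#'   early (loss to follow-up).
#' @param general_scheme_fraction probability of general-scheme coverage.
#' @param pre_window_user_fraction probability of an ibrutinib dispensation
#'   before the inclusion window (such patients are not initiators and must
#'   be excluded by the cohort stage).
#' @param post_index_diagnosis_fraction fraction of patients whose
#'   indication diagnosis is only recorded shortly after index (exercises
#'   the 30-day tail branch of the phenotyping algorithm).
#' @param noise_missing_diagnosis fraction of patients stripped of any
#'   classifiable indication diagnosis (exercises the unclassified path);
#'   default 0.
#' @param event_hazards named per-day baseline hazards: `next_treatment`,
#'   `death`, `hospitalization` (all >= 0, not all zero).
#' @param log_hazard_ratios named log-hazard ratios: `age70`, `cv`,
#'   `l2plus`, `hosp` (the latter is the time-dependent hospitalization
#'   effect).
#' @param med_initiation_probability probability of planting a post-index
#'   anticoagulant or antihypertensive start.
#' @param calendar a [study_calendar()].
#' @return validated list, class `"simulation_config"`.
#' @export
simulation_config <- function(n_patients,
                              seed = 1L,
                              disease_mix = c(CLL = 0.55, MCL = 0.22,
                                              WM = 0.15, other = 0.08),
                              age_mean = 73, age_sd = 10,
                              male_fraction = 0.61,
                              cv_comorbidity_prevalence = 0.466,
                              cv_marker_only_fraction = 0.35,
                              prior_treatment_probability = 0.80,
                              dispensation_quantity = 28L,
                              dispensation_interval_mean = 30,
                              dispensation_interval_sd = 3,
                              regimen_break_probability = 0.05,
                              regimen_break_mean = 122,
                              regimen_break_sd = 12,
                              discontinuation_rate = 1 / 600,
                              lost_to_followup_probability = 0.01,
                              general_scheme_fraction = 0.93,
                              pre_window_user_fraction = 0.02,
                              post_index_diagnosis_fraction = 0.08,
                              noise_missing_diagnosis = 0,
                              event_hazards = c(next_treatment = 3e-4,
                                                death = 1.5e-4,
                                                hospitalization = 1.5e-4),
                              log_hazard_ratios = c(age70 = 0.31, cv = 0.40,
                                                    l2plus = 0.33,
                                                    hosp = 1.11),
                              med_initiation_probability = 0.12,
                              calendar = study_calendar()) {
  cfg <- as.list(environment())
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0) {
    claims_abort("n_patients must be a single number >= 0",
                 "cllclaims_config_error")
  }
  probs <- c(male_fraction, cv_comorbidity_prevalence,
             cv_marker_only_fraction, prior_treatment_probability,
             lost_to_followup_probability, general_scheme_fraction,
             pre_window_user_fraction, post_index_diagnosis_fraction,
             noise_missing_diagnosis, med_initiation_probability,
             regimen_break_probability)
  if (any(probs < 0 | probs > 1)) {
    claims_abort("probabilities must lie in [0, 1]", "cllclaims_config_error")
  }
  need <- c("CLL", "MCL", "WM", "other")
  if (!all(need %in% names(disease_mix)) ||
      abs(sum(disease_mix) - 1) > 1e-8 || any(disease_mix < 0)) {
    claims_abort("disease_mix must be probabilities over CLL/MCL/WM/other summing to 1",
                 "cllclaims_config_error")
  }
  if (any(event_hazards < 0)) {
    claims_abort("event hazards must be >= 0", "cllclaims_config_error")
  }
  if (!all(c("next_treatment", "death", "hospitalization") %in%
             names(event_hazards))) {
    claims_abort("event_hazards must name next_treatment, death, hospitalization",
                 "cllclaims_config_error")
  }
  if (!all(c("age70", "cv", "l2plus", "hosp") %in%
             names(log_hazard_ratios))) {
    claims_abort("log_hazard_ratios must name age70, cv, l2plus, hosp",
                 "cllclaims_config_error")
  }
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

# Per-patient substream: a small deterministic seed derived from the run
# seed and the patient counter, so generation is order-independent.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 9973) %% 2147483629)
}

CV_SUBTYPE_CODES <- list(
  disabling_stroke = "I64",
  chronic_arterial_disease = "I702",
  heart_failure_arrhythmia_valvular = "I500",
  severe_hypertension = "I10",
  coronary_artery_disease = "I251"
)
CV_SUBTYPE_WEIGHTS <- c(0.05, 0.09, 0.28, 0.35, 0.23)

SAFETY_EVENT_CODES <- c(atrial_fibrillation = "I480", hypertension = "I10",
                        bleeding = "K920", cardiac_arrest = "I460",
                        paroxysmal_tachycardia = "I470",
                        heart_failure = "I500")
SAFETY_EVENT_WEIGHTS <- c(0.33, 0.03, 0.35, 0.015, 0.005, 0.27)

DISEASE_CODES <- c(CLL = "C911", MCL = "C831", WM = "C880", other = "C859")

# Piecewise-exponential event time with a single rate change at t_switch
# (rate1 before, rate2 after).  Returns Inf when both rates are zero.
piecewise_exp <- function(u_exp, rate1, rate2, t_switch) {
  if (rate1 <= 0 && rate2 <= 0) return(Inf)
  if (rate1 <= 0) return(t_switch + u_exp / rate2)
  t1 <- u_exp / rate1
  if (t1 <= t_switch || rate2 <= 0) {
    if (t1 <= t_switch) t1 else Inf
  } else {
    t_switch + (u_exp - rate1 * t_switch) / rate2
  }
}

#' Generate a synthetic claims bundle with ground truth
#'
#' Deterministic for a fixed seed.  Every simulated patient's dispensations
#' are consistent with their true regimen intervals; indication diagnoses
#' are planted with the CLL/MCL/WM codes; deaths are recorded in the
#' patients table.  The ground truth records, per patient, the quantities
#' each downstream stage is supposed to recover.
#'
#' @param config a [simulation_config()].
#' @return list with `bundle` (a [claims_bundle()]) and `truth` (class
#'   `"ground_truth"`: `patients` data.frame and `regimens` data.frame).
#' @export
generate_claims <- function(config) {
  if (!inherits(config, "simulation_config")) {
    claims_abort("config must be a simulation_config", "cllclaims_config_error")
  }
  cal <- config$calendar
  n <- config$n_patients

  pat_rows <- vector("list", n)
  disp_rows <- vector("list", n)
  stay_rows <- vector("list", n)
  ltd_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  truth_reg_rows <- vector("list", n)

  for (i in seq_len(n)) {
    g <- generate_patient(i, config, cal)
    pat_rows[[i]] <- g$patient
    disp_rows[[i]] <- g$dispensations
    stay_rows[[i]] <- g$stays
    ltd_rows[[i]] <- g$ltd
    truth_rows[[i]] <- g$truth
    truth_reg_rows[[i]] <- g$truth_regimens
  }

  rbind_or_empty <- function(rows, empty) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }

  bundle <- claims_bundle(
    patients = rbind_or_empty(pat_rows, empty_patients()),
    dispensations = rbind_or_empty(disp_rows, empty_dispensations()),
    stays = rbind_or_empty(stay_rows, empty_stays()),
    ltd_statuses = rbind_or_empty(ltd_rows, empty_ltd()),
    calendar = cal
  )
  truth <- structure(
    list(
      patients = rbind_or_empty(truth_rows, data.frame()),
      regimens = rbind_or_empty(truth_reg_rows, data.frame())
    ),
    class = "ground_truth"
  )
  list(bundle = bundle, truth = truth)
}

# Generate one patient.  All randomness is drawn from the patient's own
# substream so the result is independent of generation order.
generate_patient <- function(i, config, cal) {
  set.seed(derive_seed(config$seed, i))
  id <- sprintf("P%06d", i)
  lhr <- config$log_hazard_ratios
  hz <- config$event_hazards

  sex <- if (stats::runif(1) < config$male_fraction) "male" else "female"
  disease <- sample(names(config$disease_mix), 1,
                    prob = config$disease_mix)
  covered <- stats::runif(1) < config$general_scheme_fraction
  pre_window_user <- stats::runif(1) < config$pre_window_user_fraction
  noised <- stats::runif(1) < config$noise_missing_diagnosis

  window_days <- as.numeric(cal$inclusion_end - cal$inclusion_start)
  index <- cal$inclusion_start +
    floor(stats::runif(1) * (window_days + 1))

  age_target <- max(35, min(95, stats::rnorm(1, config$age_mean,
                                             config$age_sd)))
  birth_date <- index - round((age_target + 0.5) * DAYS_PER_YEAR)
  birth_ym <- format(birth_date, "%Y-%m")
  age <- age_at_date(birth_ym, index)

  cv <- stats::runif(1) < config$cv_comorbidity_prevalence
  cv_marker_only <- cv && stats::runif(1) < config$cv_marker_only_fraction
  l2plus <- stats::runif(1) < config$prior_treatment_probability
  ltfu <- stats::runif(1) < config$lost_to_followup_probability

  # ---- event times (days from index) under proportional hazards --------
  xb <- lhr[["age70"]] * (age >= 70) + lhr[["cv"]] * cv +
    lhr[["l2plus"]] * l2plus
  rate_nt <- hz[["next_treatment"]] * exp(xb)
  rate_d <- hz[["death"]] * exp(xb)
  rate_h <- hz[["hospitalization"]] * exp(lhr[["cv"]] * cv)
  t_hosp <- if (rate_h > 0) stats::rexp(1) / rate_h else Inf
  bump <- exp(lhr[["hosp"]])
  t_nt <- piecewise_exp(stats::rexp(1), rate_nt, rate_nt * bump, t_hosp)
  t_death <- piecewise_exp(stats::rexp(1), rate_d, rate_d * bump, t_hosp)

  horizon <- as.numeric(cal$study_end - index)
  # loss to follow-up only qualifies when the care gap fits before study end
  t_stop_care <- Inf
  if (ltfu && horizon > 300) {
    t_stop_care <- floor(stats::runif(1, 60, horizon - 200))
  }
  obs_limit <- min(horizon, t_stop_care)

  cause <- "censored"
  death_date <- as.Date(NA_character_)
  next_date <- as.Date(NA_character_)
  t_event <- Inf
  if (min(t_nt, t_death) <= obs_limit) {
    # ties broken toward death (the rarer cause)
    if (t_death <= t_nt) {
      cause <- "death"
      t_event <- max(1, min(round(t_death), floor(obs_limit)))
      death_date <- index + t_event
    } else {
      cause <- "next_treatment"
      t_event <- max(1, min(round(t_nt), floor(obs_limit)))
      next_date <- index + t_event
    }
  }

  followup_days <- if (cause == "death") t_event else floor(obs_limit)
  followup_end <- index + followup_days
  followup_reason <- if (cause == "death") "death"
    else if (is.finite(t_stop_care) && t_stop_care < horizon)
      "lost_to_followup"
    else "end_of_study"

  # ---- ibrutinib treatment timeline ------------------------------------
  q <- config$dispensation_quantity
  persistence <- stats::rexp(1) / config$discontinuation_rate
  treat_end <- min(persistence, followup_days)
  if (cause == "next_treatment") {
    gap_before_next <- stats::runif(1, 35, 180)
    treat_end <- min(treat_end, t_event - gap_before_next)
  }
  treat_end <- max(0, treat_end)

  # optional single break (second regimen)
  break_at <- Inf
  break_len <- 0
  if (stats::runif(1) < config$regimen_break_probability &&
      treat_end > 250) {
    break_at <- stats::runif(1, 0.2, 0.6) * treat_end
    break_len <- round(max(95, min(160, stats::rnorm(
      1, config$regimen_break_mean, config$regimen_break_sd))))
  }

  ibru_days <- numeric(0)
  seg_of <- integer(0)
  d <- 0
  seg <- 1L
  repeat {
    if (d > treat_end) break
    if (d > break_at) {
      # jump over the planned break: previous dispensation ended segment 1
      d <- ibru_days[length(ibru_days)] + q + break_len
      break_at <- Inf
      seg <- 2L
      if (d > treat_end) break
    }
    ibru_days <- c(ibru_days, d)
    seg_of <- c(seg_of, seg)
    step <- round(max(21, min(45, stats::rnorm(
      1, config$dispensation_interval_mean,
      config$dispensation_interval_sd))))
    d <- d + step
  }
  n_regimens <- length(unique(seg_of))
  ibru_dates <- index + ibru_days
  truth_regs <- NULL
  if (length(ibru_days)) {
    truth_regs <- do.call(rbind, lapply(unique(seg_of), function(s) {
      dd <- ibru_days[seg_of == s]
      data.frame(
        patient_id = id, ordinal = s,
        start_date = index + min(dd),
        coverage_end_date = pmin(index + max(dd) + q - 1, followup_end),
        n_dispensations = length(dd), stringsAsFactors = FALSE
      )
    }))
  }
  coverage_end <- if (length(ibru_days)) {
    min(index + max(ibru_days) + q - 1, followup_end)
  } else index

  disp <- list(data.frame(patient_id = id, date = ibru_dates,
                          atc_code = "L01EL01",
                          quantity = as.integer(q),
                          stringsAsFactors = FALSE))
  stays <- list()
  ltd <- list()

  if (pre_window_user) {
    d0 <- cal$inclusion_start - sample(30:400, 1)
    disp[[length(disp) + 1L]] <- data.frame(
      patient_id = id, date = d0, atc_code = "L01EL01",
      quantity = as.integer(q), stringsAsFactors = FALSE)
  }

  # ---- indication diagnosis --------------------------------------------
  post_index_dx <- stats::runif(1) < config$post_index_diagnosis_fraction &&
    followup_days >= 12
  if (!noised) {
    code <- DISEASE_CODES[[disease]]
    if (post_index_dx) {
      dx_date <- index + sample(1:10, 1)
      stays[[length(stays) + 1L]] <- data.frame(
        patient_id = id, admission_date = dx_date,
        discharge_date = dx_date + sample(1:5, 1),
        main_dx = code, related_dx = "", associated_dx = "",
        device_codes = "", stringsAsFactors = FALSE)
    } else if (stats::runif(1) < 0.7) {
      ltd[[length(ltd) + 1L]] <- data.frame(
        patient_id = id, icd10_code = code,
        start_date = pmax(cal$study_start + 1,
                          index - sample(200:3000, 1)),
        stringsAsFactors = FALSE)
    } else {
      dx_date <- pmax(cal$study_start + 1, index - sample(30:330, 1))
      stays[[length(stays) + 1L]] <- data.frame(
        patient_id = id, admission_date = dx_date,
        discharge_date = dx_date + sample(1:7, 1),
        main_dx = code, related_dx = "", associated_dx = "",
        device_codes = "", stringsAsFactors = FALSE)
    }
  }

  # ---- cardiovascular comorbidity --------------------------------------
  if (cv && !cv_marker_only) {
    sub <- sample(names(CV_SUBTYPE_CODES), 1, prob = CV_SUBTYPE_WEIGHTS)
    code <- CV_SUBTYPE_CODES[[sub]]
    if (stats::runif(1) < 0.5) {
      ltd[[length(ltd) + 1L]] <- data.frame(
        patient_id = id, icd10_code = code,
        start_date = pmax(cal$study_start + 1,
                          index - sample(200:2000, 1)),
        stringsAsFactors = FALSE)
    } else {
      dx_date <- index - sample(30:330, 1)
      stays[[length(stays) + 1L]] <- data.frame(
        patient_id = id, admission_date = dx_date,
        discharge_date = dx_date + sample(1:7, 1),
        main_dx = code, related_dx = "", associated_dx = "",
        device_codes = "", stringsAsFactors = FALSE)
    }
  }
  if (cv_marker_only) {
    marker_atc <- if (stats::runif(1) < 0.5) "B01AA03" else "B01AC06"
    disp[[length(disp) + 1L]] <- data.frame(
      patient_id = id, date = index - c(300L, 200L, 100L),
      atc_code = marker_atc, quantity = 30L, stringsAsFactors = FALSE)
  }

  # ---- prior CLL-specific treatment (line) -----------------------------
  first_treat <- as.Date(NA_character_)
  if (l2plus) {
    yrs <- stats::runif(1, 0.5, 11)
    first_treat <- pmax(cal$study_start + 1,
                        index - round(yrs * DAYS_PER_YEAR))
    disp[[length(disp) + 1L]] <- data.frame(
      patient_id = id, date = first_treat, atc_code = "L01FA01",
      quantity = 1L, stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.5) {
      disp[[length(disp) + 1L]] <- data.frame(
        patient_id = id, date = first_treat, atc_code = "SESSION",
        quantity = 1L, stringsAsFactors = FALSE)
    }
  }

  # ---- next treatment --------------------------------------------------
  if (cause == "next_treatment") {
    disp[[length(disp) + 1L]] <- data.frame(
      patient_id = id, date = next_date, atc_code = "L01XX52",
      quantity = 1L, stringsAsFactors = FALSE)
  }

  # ---- safety hospitalization during exposure --------------------------
  hosp_time <- NA_real_
  hosp_category <- NA_character_
  t_h_day <- if (is.finite(t_hosp)) max(1, round(t_hosp)) else Inf
  if (is.finite(t_h_day) &&
      index + t_h_day <= coverage_end &&
      t_h_day <= followup_days) {
    hosp_category <- sample(names(SAFETY_EVENT_CODES), 1,
                            prob = SAFETY_EVENT_WEIGHTS)
    adm <- index + t_h_day
    dur <- 1L + stats::rpois(1, 5)
    dis <- min(adm + dur, followup_end)
    stays[[length(stays) + 1L]] <- data.frame(
      patient_id = id, admission_date = adm, discharge_date = dis,
      main_dx = SAFETY_EVENT_CODES[[hosp_category]], related_dx = "",
      associated_dx = "", device_codes = "", stringsAsFactors = FALSE)
    hosp_time <- t_h_day
  }

  # ---- post-index cardiovascular medication ----------------------------
  if (stats::runif(1) < config$med_initiation_probability &&
      followup_days > 40) {
    med_atc <- if (stats::runif(1) < 0.5) "B01AF01" else "C09AA05"
    med_day <- sample(30:min(300, followup_days), 1)
    disp[[length(disp) + 1L]] <- data.frame(
      patient_id = id, date = index + med_day, atc_code = med_atc,
      quantity = 30L, stringsAsFactors = FALSE)
  }

  # ---- routine care keeping the patient observable ---------------------
  care_days <- seq(7, max(7, followup_days), by = 55)
  care_days <- care_days[care_days <= followup_days]
  if (length(care_days)) {
    disp[[length(disp) + 1L]] <- data.frame(
      patient_id = id, date = index + care_days, atc_code = "N02BE01",
      quantity = 16L, stringsAsFactors = FALSE)
  }
  # a final care record at the end of follow-up anchors the follow-up
  # computation (last dispensing before death / loss to follow-up / study end)
  if (followup_days > 0) {
    disp[[length(disp) + 1L]] <- data.frame(
      patient_id = id, date = followup_end, atc_code = "A02BC01",
      quantity = 14L, stringsAsFactors = FALSE)
  }

  disp <- do.call(rbind, disp)
  disp <- disp[disp$date >= cal$study_start & disp$date <= cal$study_end, ,
               drop = FALSE]
  # nothing (except the death record) may trail the end of follow-up
  disp <- disp[disp$date <= followup_end, , drop = FALSE]
  disp <- disp[radix_order(as.numeric(disp$date), disp$atc_code), ,
               drop = FALSE]

  patient <- data.frame(
    patient_id = id, sex = sex, birth_year_month = birth_ym,
    death_date = death_date, general_scheme_covered = covered,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = id, disease = disease, age = age, sex = sex,
    cv_comorbidity = cv, cv_marker_only = cv_marker_only,
    line = if (l2plus) "L2plus" else "L1",
    first_cll_treatment_date = first_treat,
    n_regimens = n_regimens,
    index_date = index, followup_end = followup_end,
    followup_reason = followup_reason,
    coverage_end_date = coverage_end,
    death_date = death_date, next_treatment_date = next_date,
    event_cause = cause,
    hosp_time_days = hosp_time, hosp_category = hosp_category,
    covered = covered, pre_window_user = pre_window_user,
    noised = noised,
    expected_included = covered && !pre_window_user &&
      (followup_days > 0 || !is.na(death_date)),
    stringsAsFactors = FALSE
  )
  list(patient = patient, dispensations = disp,
       stays = if (length(stays)) do.call(rbind, stays) else NULL,
       ltd = if (length(ltd)) do.call(rbind, ltd) else NULL,
       truth = truth, truth_regimens = truth_regs)
}

#' Simulate a counting-process survival benchmark with known effects
#'
#' Generates exponential event times under proportional hazards with two
#' fixed binary covariates (`x1`, `x2`) and one time-dependent covariate
#' (`hosp`, switching at an independently simulated hospitalization time),
#' administratively censored at `censor_horizon`.  Event times are
#' continuous, so the benchmark is tie-free.  Used to verify that the Cox
#' fitter recovers known log-hazard ratios with nominal confidence-interval
#' coverage.
#'
#' @param n number of subjects.
#' @param true_log_hr named numeric: `x1`, `x2`, `hosp`.
#' @param baseline_hazard named per-day hazards: `event`,
#'   `hospitalization`; must not both be zero.
#' @param covariate_prevalence named probabilities for `x1`, `x2`.
#' @param censor_horizon administrative censoring time (days).
#' @param seed integer seed.
#' @return list with `records` (counting-process data.frame: `id`, `entry`,
#'   `exit`, `event`, `x1`, `x2`, `hosp`) and `true_betas`.
#' @export
generate_survival_benchmark <- function(n,
                                        true_log_hr = c(x1 = 0.4, x2 = -0.4,
                                                        hosp = 1.1),
                                        baseline_hazard = c(
                                          event = 0.002,
                                          hospitalization = 0.0015),
                                        covariate_prevalence = c(x1 = 0.5,
                                                                 x2 = 0.4),
                                        censor_horizon = 730,
                                        seed = 1L) {
  if (all(baseline_hazard <= 0)) {
    claims_abort("all-zero baseline hazards", "cllclaims_config_error")
  }
  if (baseline_hazard[["event"]] <= 0) {
    claims_abort("event baseline hazard must be > 0",
                 "cllclaims_config_error")
  }
  set.seed(as.integer(seed))
  x1 <- as.integer(stats::runif(n) < covariate_prevalence[["x1"]])
  x2 <- as.integer(stats::runif(n) < covariate_prevalence[["x2"]])
  rate0 <- baseline_hazard[["event"]] *
    exp(true_log_hr[["x1"]] * x1 + true_log_hr[["x2"]] * x2)
  rate_h <- baseline_hazard[["hospitalization"]]
  t_h <- if (rate_h > 0) stats::rexp(n) / rate_h else rep(Inf, n)
  u <- stats::rexp(n)
  bump <- exp(true_log_hr[["hosp"]])
  t_ev <- vapply(seq_len(n), function(i) {
    piecewise_exp(u[i], rate0[i], rate0[i] * bump, t_h[i])
  }, numeric(1))

  exit <- pmin(t_ev, censor_horizon)
  event <- as.integer(t_ev <= censor_horizon)
  sp <- is.finite(t_h) & t_h < exit & t_h > 0
  part <- function(ids, entry, exit, event, hosp) {
    data.frame(id = ids, entry = entry, exit = exit, event = event,
               x1 = x1[ids], x2 = x2[ids], hosp = rep(hosp, length(ids)))
  }
  records <- rbind(
    part(which(sp), rep(0, sum(sp)), t_h[sp], rep(0L, sum(sp)), 0L),
    part(which(sp), t_h[sp], exit[sp], event[sp], 1L),
    part(which(!sp), rep(0, sum(!sp)), exit[!sp], event[!sp], 0L)
  )
  records <- records[order(records$id, records$entry), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, true_betas = true_log_hr)
}
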