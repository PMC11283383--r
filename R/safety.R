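# Safety module: hospitalizations for cardiovascular / bleeding events
# during ibrutinib exposure, post-event treatment continuation, and
# cardiovascular-medication initiation in the year after index.

#' Detect event hospitalizations during ibrutinib exposure
#'
#' Scans hospital stays admitted during the exposure period (first regimen
#' start through the last regimen's coverage end) whose main or related
#' discharge diagnosis matches one of the six event categories (atrial
#' fibrillation, hypertension, bleeding, cardiac arrest, paroxysmal
#' tachycardia, heart failure).  Associated diagnoses are deliberately not
#' consulted.  One record is produced per (stay, category).
#'
#' @param index_date index date.
#' @param regimens [build_regimens()] output for the patient.
#' @param stays the patient's hospital stay rows.
#' @param codemap a [load_codemap()] list (uses its `safety_events`).
#' @return data.frame `category`, `admission_date`, `discharge_date`,
#'   `duration_days`, `months_from_index`, sorted by admission then
#'   category.
#' @export
detect_event_hospitalizations <- function(index_date, regimens, stays,
                                          codemap = load_codemap()) {
  empty <- data.frame(category = character(0),
                      admission_date = as.Date(character(0)),
                      discharge_date = as.Date(character(0)),
                      duration_days = numeric(0),
                      months_from_index = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(regimens) == 0L || nrow(stays) == 0L) return(empty)
  exp_start <- regimens$start_date[1]
  exp_end <- regimens$coverage_end_date[nrow(regimens)]
  st <- stays[stays$admission_date >= exp_start &
                stays$admission_date <= exp_end, , drop = FALSE]
  if (nrow(st) == 0L) return(empty)

  rows <- list()
  for (i in seq_len(nrow(st))) {
    codes <- stay_codes(st[i, , drop = FALSE], positions = "main_related")
    for (cat in names(codemap$safety_events)) {
      if (any(match_any_prefix(codes, codemap$safety_events[[cat]]))) {
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat,
          admission_date = st$admission_date[i],
          discharge_date = st$discharge_date[i],
          duration_days = as.numeric(st$discharge_date[i] -
                                       st$admission_date[i]),
          months_from_index = days_to_months(
            as.numeric(st$admission_date[i] - index_date)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$admission_date, out$category, method = "radix"), ,
      drop = FALSE]
}

#' Ibrutinib continuation after the first event hospitalization
#'
#' @param events [detect_event_hospitalizations()] output (>= 1 row).
#' @param ibrutinib_dates `Date` vector of the patient's ibrutinib
#'   dispensations.
#' @param followup_end end of follow-up.
#' @return list with `continued` (logical) and `delay_days` (days from
#'   first-event discharge to the following dispensation, or `NA`).
#' @export
continued_after_event <- function(events, ibrutinib_dates, followup_end) {
  if (nrow(events) == 0L) {
    claims_abort("continued_after_event requires at least one event",
                 "cllclaims_config_error")
  }
  first <- events[which.min(events$admission_date), , drop = FALSE]
  after <- ibrutinib_dates[ibrutinib_dates >= first$discharge_date &
                             ibrutinib_dates <= followup_end]
  if (length(after) == 0L) {
    return(list(continued = FALSE, delay_days = NA_real_))
  }
  list(continued = TRUE,
       delay_days = as.numeric(min(after) - first$discharge_date))
}

#' Cardiovascular-medication initiation in the year after index
#'
#' Anticoagulants and antiplatelets: initiation iff at least one
#' dispensation in the 12 months after index and none in the 12 months
#' before (new user).  Antihypertensives: the same new-user rule, or an
#' add-on -- the number of distinct ATC level-3 antihypertensive classes
#' dispensed post-index exceeds the pre-index count and reaches 2 or 3
#' (a second or third agent added).
#'
#' @param index_date index date.
#' @param dispensations the patient's dispensation rows.
#' @param codes a [default_drug_codes()] list.
#' @return one-row data.frame with logical flags
#'   `antihypertensive_initiation_or_addon`, `anticoagulant_initiation`,
#'   `antiplatelet_initiation`, `any`.
#' @export
medication_initiation <- function(index_date, dispensations,
                                  codes = default_drug_codes()) {
  pre <- dispensations[dispensations$date >= index_date - 365L &
                         dispensations$date < index_date, , drop = FALSE]
  post <- dispensations[dispensations$date > index_date &
                          dispensations$date <= index_date + 365L, ,
                        drop = FALSE]
  new_user <- function(prefixes) {
    any(match_any_prefix(post$atc_code, prefixes)) &&
      !any(match_any_prefix(pre$atc_code, prefixes))
  }
  ac <- new_user(codes$anticoagulant)
  ap <- new_user(codes$antiplatelet)

  aht_classes <- function(df) {
    cls <- substr(df$atc_code, 1L, 3L)
    unique(cls[cls %in% codes$antihypertensive_classes])
  }
  pre_cls <- aht_classes(pre)
  post_cls <- aht_classes(post)
  aht_init <- length(post_cls) > 0L && length(pre_cls) == 0L
  aht_addon <- length(post_cls) > length(pre_cls) &&
    length(post_cls) %in% 2:3
  aht <- aht_init || aht_addon

  data.frame(antihypertensive_initiation_or_addon = aht,
             anticoagulant_initiation = ac,
             antiplatelet_initiation = ap,
             any = aht || ac || ap,
             stringsAsFactors = FALSE)
}
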