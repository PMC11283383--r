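# Cohort selection for new users of ibrutinib, follow-up computation, and
# the indication phenotyping algorithm (CLL / MCL / WM).
#
# A patient is an includable initiator iff
#   (a) their first-ever ibrutinib dispensation falls inside the inclusion
#       window (community-pharmacy availability through end of study);
#   (b) they are covered by the general insurance scheme over the whole
#       study history;
#   (c) they have at least one other care record after the index date, or
#       died (patients leaving no trace after the first dispensation are
#       unobservable and excluded).
# The index date is the first ibrutinib dispensation.

INDICATION_CODES <- c(CLL = "C911", MCL = "C831", WM = "C880")

#' Compute end of follow-up for one patient
#'
#' Follow-up runs from the index date until the earliest of: administrative
#' end of study, death, or loss to follow-up -- defined as the last care
#' record before a period of more than `gap_days` without any reimbursed
#' care.  A death occurring before a care gap has fully elapsed takes
#' precedence over the loss-to-follow-up bound.
#'
#' @param index_date index date (`Date`).
#' @param death_date death date or `NA`.
#' @param care_dates `Date` vector of all care records (dispensations, stay
#'   admissions, LTD starts) for the patient.
#' @param study_end administrative end of study.
#' @param gap_days care gap (in days) that qualifies as loss to follow-up;
#'   default 183 (six months).
#' @return list with `followup_end` (`Date`) and `reason` (one of
#'   `"end_of_study"`, `"death"`, `"lost_to_followup"`).
#' @export
compute_followup <- function(index_date, death_date, care_dates, study_end,
                             gap_days = 183L) {
  care <- sort(unique(care_dates[!is.na(care_dates) & care_dates >= index_date]))
  care <- care[care <= study_end]
  if (length(care) == 0L) care <- index_date
  has_death <- !is.na(death_date)

  # first care record followed by a gap > gap_days; for the last record the
  # observable care-free period ends at the study end
  nxt <- c(care[-1], study_end)
  gap_idx <- which(as.numeric(nxt - care) > gap_days)
  ltfu_end <- as.Date(NA_character_)
  if (length(gap_idx)) {
    cand <- care[gap_idx[1]]
    # a death within the qualifying gap takes precedence
    if (!(has_death && death_date <= cand + gap_days)) ltfu_end <- cand
  }

  bounds <- c(end_of_study = as.numeric(study_end),
              death = if (has_death) as.numeric(death_date) else Inf,
              lost_to_followup = if (!is.na(ltfu_end)) as.numeric(ltfu_end)
                                 else Inf)
  # tie priority: death, then end_of_study
  priority <- c(death = 1L, end_of_study = 2L, lost_to_followup = 3L)
  best <- names(bounds)[order(bounds, priority[names(bounds)])][1]
  list(followup_end = as.Date(bounds[[best]], origin = "1970-01-01"),
       reason = best)
}

#' Classify the indication for ibrutinib (CLL / MCL / WM)
#'
#' Dated diagnoses bearing the CLL (C91.1), MCL (C83.1) or WM (C88.0) codes
#' are collected from LTD statuses and all hospital diagnosis positions.
#' If any diagnosis predates the index, the label of the latest such
#' diagnosis wins; otherwise the earliest diagnosis dated up to
#' `post_window_days` after the last ibrutinib dispensation wins; otherwise
#' the patient is `"unclassified"`.  Two different disease codes on the same
#' qualifying date also yield `"unclassified"` (the algorithm is restrictive
#' by design).
#'
#' @param index_date index date.
#' @param last_ibrutinib_date date of the patient's last ibrutinib
#'   dispensation.
#' @param ltd patient's LTD rows.
#' @param stays patient's hospital stay rows.
#' @param post_window_days tail window after the last dispensation (default
#'   30).
#' @return one of `"CLL"`, `"MCL"`, `"WM"`, `"unclassified"`.
#' @export
classify_indication <- function(index_date, last_ibrutinib_date, ltd, stays,
                                post_window_days = 30L) {
  dates <- as.Date(character(0))
  codes <- character(0)
  if (nrow(ltd)) {
    dates <- c(dates, ltd$start_date)
    codes <- c(codes, norm_icd(ltd$icd10_code))
  }
  if (nrow(stays)) {
    for (col in c("main_dx", "related_dx", "associated_dx")) {
      v <- stays[[col]]
      keep <- !is.na(v) & nzchar(v)
      if (any(keep)) {
        parts <- strsplit(v[keep], ";", fixed = TRUE)
        dates <- c(dates, rep(stays$admission_date[keep],
                              lengths(parts)))
        codes <- c(codes, norm_icd(unlist(parts)))
      }
    }
  }
  lab <- rep(NA_character_, length(codes))
  for (d in names(INDICATION_CODES)) {
    lab[startsWith(codes, INDICATION_CODES[[d]])] <- d
  }
  keep <- !is.na(lab)
  dates <- dates[keep]; lab <- lab[keep]
  if (length(lab) == 0L) return("unclassified")

  pre <- dates < index_date
  if (any(pre)) {
    dmax <- max(dates[pre])
    labels <- unique(lab[pre & dates == dmax])
    return(if (length(labels) == 1L) labels else "unclassified")
  }
  cutoff <- last_ibrutinib_date + post_window_days
  post <- dates <= cutoff
  if (any(post)) {
    dmin <- min(dates[post])
    labels <- unique(lab[post & dates == dmin])
    return(if (length(labels) == 1L) labels else "unclassified")
  }
  "unclassified"
}

#' Select the ibrutinib new-user cohort
#'
#' Applies the inclusion/exclusion cascade, sets the index date (first
#' ibrutinib dispensation), computes follow-up and classifies the indication
#' for every included patient.  Each excluded patient is counted once, under
#' the first criterion that fails, so the flowchart tally conserves counts
#' at every step.
#'
#' @param bundle a validated [claims_bundle()].
#' @param ibrutinib_atc ATC code of ibrutinib (default `"L01EL01"`).
#' @param gap_days loss-to-follow-up care gap, see [compute_followup()].
#' @param post_window_days indication tail window, see
#'   [classify_indication()].
#' @return list with `members` (one row per included patient: `patient_id`,
#'   `index_date`, `last_ibrutinib_date`, `followup_end`, `followup_reason`,
#'   `indication`) and `flowchart` (a `"flowchart_tally"`).
#' @export
select_cohort <- function(bundle, ibrutinib_atc = "L01EL01",
                          gap_days = 183L, post_window_days = 30L) {
  cal <- bundle$calendar
  disp <- bundle$dispensations
  ibru <- disp[disp$atc_code %in% ibrutinib_atc, , drop = FALSE]

  steps <- list()
  candidates <- unique(ibru$patient_id)
  candidates <- candidates[radix_order(candidates)]
  n0 <- length(candidates)

  first_ibru <- tapply(as.numeric(ibru$date), ibru$patient_id, min)
  last_ibru <- tapply(as.numeric(ibru$date), ibru$patient_id, max)
  fi <- as.Date(first_ibru[candidates], origin = "1970-01-01")

  in_window <- fi >= cal$inclusion_start & fi <= cal$inclusion_end
  steps[[1]] <- list(
    step = "first ibrutinib dispensation within inclusion window",
    n_before = n0, n_excluded = sum(!in_window))
  keep <- candidates[in_window]

  pat <- bundle$patients
  covered <- pat$general_scheme_covered[match(keep, pat$patient_id)]
  steps[[2]] <- list(step = "covered by general insurance scheme",
                     n_before = length(keep), n_excluded = sum(!covered))
  keep <- keep[covered]

  # care records after index (any dispensation, stay or LTD start), or death
  by_pat <- function(df, datecol) split(df[[datecol]], df$patient_id)
  disp_by <- by_pat(disp, "date")
  stay_by <- by_pat(bundle$stays, "admission_date")
  ltd_by <- by_pat(bundle$ltd_statuses, "start_date")
  death <- pat$death_date[match(keep, pat$patient_id)]

  has_care_after <- vapply(seq_along(keep), function(i) {
    id <- keep[i]
    idx <- first_ibru[[id]]
    cd <- c(as.numeric(disp_by[[id]]), as.numeric(stay_by[[id]]),
            as.numeric(ltd_by[[id]]))
    any(cd > idx) || !is.na(death[i])
  }, logical(1))
  steps[[3]] <- list(step = "care recorded after index date (or death)",
                     n_before = length(keep),
                     n_excluded = sum(!has_care_after))
  keep <- keep[has_care_after]

  stays_by_df <- split(bundle$stays, bundle$stays$patient_id)
  ltd_by_df <- split(bundle$ltd_statuses, bundle$ltd_statuses$patient_id)

  members <- data.frame(
    patient_id = keep,
    index_date = as.Date(first_ibru[keep], origin = "1970-01-01"),
    last_ibrutinib_date = as.Date(last_ibru[keep], origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  if (nrow(members)) {
    death_k <- pat$death_date[match(keep, pat$patient_id)]
    fu <- lapply(seq_len(nrow(members)), function(i) {
      id <- members$patient_id[i]
      care <- as.Date(c(as.numeric(disp_by[[id]]), as.numeric(stay_by[[id]]),
                        as.numeric(ltd_by[[id]])), origin = "1970-01-01")
      compute_followup(members$index_date[i], death_k[i], care,
                       cal$study_end, gap_days = gap_days)
    })
    members$followup_end <- as.Date(
      vapply(fu, function(z) as.numeric(z$followup_end), numeric(1)),
      origin = "1970-01-01")
    members$followup_reason <- vapply(fu, `[[`, character(1), "reason")
    empty_stay <- empty_stays(); empty_l <- empty_ltd()
    members$indication <- vapply(seq_len(nrow(members)), function(i) {
      id <- members$patient_id[i]
      classify_indication(members$index_date[i],
                          members$last_ibrutinib_date[i],
                          ltd_by_df[[id]] %||% empty_l,
                          stays_by_df[[id]] %||% empty_stay,
                          post_window_days = post_window_days)
    }, character(1))
  } else {
    members$followup_end <- as.Date(character(0))
    members$followup_reason <- character(0)
    members$indication <- character(0)
  }

  tally <- structure(
    list(
      steps = data.frame(
        step = vapply(steps, `[[`, character(1), "step"),
        n_before = vapply(steps, `[[`, numeric(1), "n_before"),
        n_excluded = vapply(steps, `[[`, numeric(1), "n_excluded"),
        n_after = vapply(steps, function(s) s$n_before - s$n_excluded,
                         numeric(1)),
        stringsAsFactors = FALSE
      ),
      indication_counts = {
        counts <- table(factor(members$indication,
                               levels = c("CLL", "MCL", "WM", "unclassified")))
        stats::setNames(as.integer(counts), names(counts))
      },
      n_included = nrow(members)
    ),
    class = "flowchart_tally"
  )
  list(members = members, flowchart = tally)
}

#' @export
print.flowchart_tally <- function(x, ...) {
  cat("<flowchart_tally>\n")
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %-55s %6d -> %6d (excluded %d)\n",
                x$steps$step[i], x$steps$n_before[i], x$steps$n_after[i],
                x$steps$n_excluded[i]))
  }
  cat("  indication: ",
      paste(sprintf("%s=%d", names(x$indication_counts), x$indication_counts),
            collapse = ", "), "\n")
  invisible(x)
}
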