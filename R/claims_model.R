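# Claims data model: the four SNDS-like tables, the study calendar,
# validation, and delimited-file readers/writers.
#
# Tables (all plain data.frames, dates as `Date`):
#   patients:       patient_id, sex, birth_year_month, death_date,
#                   general_scheme_covered
#   dispensations:  patient_id, date, atc_code, quantity
#   stays:          patient_id, admission_date, discharge_date, main_dx,
#                   related_dx, associated_dx, device_codes
#                   (multi-code fields are ";"-separated strings, "" if none)
#   ltd_statuses:   patient_id, icd10_code, start_date
#
# The calendar fixes the observable history (claims history starts 2006-01-01)
# and the new-user inclusion window (community-pharmacy availability of
# ibrutinib, 2017-08-01, through end of study, 2020-12-31).

#' Study calendar for a claims bundle
#'
#' @param study_start first date of available claims history.
#' @param inclusion_start,inclusion_end window in which the first ibrutinib
#'   dispensation must fall for a patient to qualify as an initiator.
#' @param study_end administrative end of follow-up.
#' @return a list of four `Date` scalars, class `"study_calendar"`.
#' @export
study_calendar <- function(study_start = "2006-01-01",
                           inclusion_start = "2017-08-01",
                           inclusion_end = "2020-12-31",
                           study_end = "2020-12-31") {
  cal <- list(
    study_start = as.Date(study_start),
    inclusion_start = as.Date(inclusion_start),
    inclusion_end = as.Date(inclusion_end),
    study_end = as.Date(study_end)
  )
  if (any(vapply(cal, is.na, logical(1)))) {
    claims_abort("study calendar dates must be parseable ISO dates",
                 "cllclaims_config_error")
  }
  if (cal$study_start > cal$inclusion_start ||
      cal$inclusion_start > cal$inclusion_end ||
      cal$inclusion_end > cal$study_end) {
    claims_abort("study calendar dates must be ordered", "cllclaims_config_error")
  }
  structure(cal, class = "study_calendar")
}

empty_patients <- function() {
  data.frame(patient_id = character(0), sex = character(0),
             birth_year_month = character(0),
             death_date = as.Date(character(0)),
             general_scheme_covered = logical(0),
             stringsAsFactors = FALSE)
}

empty_dispensations <- function() {
  data.frame(patient_id = character(0), date = as.Date(character(0)),
             atc_code = character(0), quantity = integer(0),
             stringsAsFactors = FALSE)
}

empty_stays <- function() {
  data.frame(patient_id = character(0),
             admission_date = as.Date(character(0)),
             discharge_date = as.Date(character(0)),
             main_dx = character(0), related_dx = character(0),
             associated_dx = character(0), device_codes = character(0),
             stringsAsFactors = FALSE)
}

empty_ltd <- function() {
  data.frame(patient_id = character(0), icd10_code = character(0),
             start_date = as.Date(character(0)), stringsAsFactors = FALSE)
}

#' Assemble and validate a claims bundle
#'
#' A claims bundle holds the four linked tables plus the study calendar and is
#' the universe every pipeline stage consumes.  Construction validates all
#' structural invariants; invalid input raises a typed condition
#' (`cllclaims_schema_error`, `cllclaims_validation_error`,
#' `cllclaims_referential_error`) rather than silently coercing.
#'
#' @param patients,dispensations,stays,ltd_statuses data.frames with the
#'   columns documented in the package readme; `NULL` means an empty table.
#' @param calendar a [study_calendar()].
#' @return a validated object of class `"claims_bundle"`.
#' @export
claims_bundle <- function(patients = NULL, dispensations = NULL,
                          stays = NULL, ltd_statuses = NULL,
                          calendar = study_calendar()) {
  bundle <- structure(
    list(
      patients = patients %||% empty_patients(),
      dispensations = dispensations %||% empty_dispensations(),
      stays = stays %||% empty_stays(),
      ltd_statuses = ltd_statuses %||% empty_ltd(),
      calendar = calendar
    ),
    class = "claims_bundle"
  )
  validate_bundle(bundle)
  bundle
}

bundle_schema <- list(
  patients = c("patient_id", "sex", "birth_year_month", "death_date",
               "general_scheme_covered"),
  dispensations = c("patient_id", "date", "atc_code", "quantity"),
  stays = c("patient_id", "admission_date", "discharge_date", "main_dx",
            "related_dx", "associated_dx", "device_codes"),
  ltd_statuses = c("patient_id", "icd10_code", "start_date")
)

check_in_calendar <- function(dates, cal, what) {
  dates <- dates[!is.na(dates)]
  if (length(dates) && (any(dates < cal$study_start) ||
                        any(dates > cal$study_end))) {
    claims_abort(
      sprintf("%s outside the study calendar [%s, %s]", what,
              format(cal$study_start), format(cal$study_end)),
      "cllclaims_validation_error"
    )
  }
  invisible(NULL)
}

#' Validate the invariants of a claims bundle
#'
#' @param bundle a `"claims_bundle"` (or a list with the same shape).
#' @return the bundle, invisibly; raises a typed condition on violation.
#' @export
validate_bundle <- function(bundle) {
  for (tab in names(bundle_schema)) {
    missing <- setdiff(bundle_schema[[tab]], names(bundle[[tab]]))
    if (length(missing)) {
      claims_abort(
        sprintf("table '%s' is missing required column(s): %s", tab,
                paste(missing, collapse = ", ")),
        "cllclaims_schema_error"
      )
    }
  }
  cal <- bundle$calendar
  pat <- bundle$patients
  if (anyDuplicated(pat$patient_id)) {
    claims_abort("duplicate patient_id in patients table",
                 "cllclaims_validation_error")
  }
  bad_sex <- setdiff(unique(pat$sex), c("male", "female"))
  if (length(bad_sex)) {
    claims_abort(sprintf("invalid sex value(s): %s",
                         paste(bad_sex, collapse = ", ")),
                 "cllclaims_validation_error")
  }
  if (nrow(pat) && any(!grepl("^\\d{4}-\\d{2}$", pat$birth_year_month))) {
    claims_abort("birth_year_month must have format YYYY-MM",
                 "cllclaims_validation_error")
  }
  check_in_calendar(pat$death_date, cal, "patient death_date")

  disp <- bundle$dispensations
  if (nrow(disp)) {
    if (any(is.na(disp$quantity)) || any(disp$quantity < 1)) {
      claims_abort("dispensation quantity must be >= 1",
                   "cllclaims_validation_error")
    }
    check_in_calendar(disp$date, cal, "dispensation date")
  }

  stays <- bundle$stays
  if (nrow(stays)) {
    if (any(is.na(stays$admission_date)) || any(is.na(stays$discharge_date))) {
      claims_abort("hospital stays must have admission and discharge dates",
                   "cllclaims_validation_error")
    }
    if (any(stays$discharge_date < stays$admission_date)) {
      claims_abort("hospital stay discharge before admission",
                   "cllclaims_validation_error")
    }
    check_in_calendar(stays$admission_date, cal, "stay admission date")
  }

  ltd <- bundle$ltd_statuses
  if (nrow(ltd)) check_in_calendar(ltd$start_date, cal, "LTD start date")

  # referential integrity
  known <- pat$patient_id
  for (tab in c("dispensations", "stays", "ltd_statuses")) {
    orphan <- setdiff(unique(bundle[[tab]]$patient_id), known)
    if (length(orphan)) {
      claims_abort(
        sprintf("table '%s' references unknown patient_id(s): %s", tab,
                paste(utils::head(orphan, 5), collapse = ", ")),
        "cllclaims_referential_error"
      )
    }
  }

  # birth precedes all care dates
  if (nrow(pat)) {
    birth <- as.Date(paste0(pat$birth_year_month, "-01"))
    names(birth) <- pat$patient_id
    care_min <- c(
      tapply(as.numeric(disp$date), disp$patient_id, min),
      tapply(as.numeric(stays$admission_date), stays$patient_id, min),
      tapply(as.numeric(ltd$start_date), ltd$patient_id, min)
    )
    if (length(care_min)) {
      care_min <- tapply(care_min, names(care_min), min)
      if (any(as.numeric(birth[names(care_min)]) >= care_min)) {
        claims_abort("care recorded before patient birth",
                     "cllclaims_validation_error")
      }
    }
  }
  invisible(bundle)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  patients:      %d\n", nrow(x$patients)))
  cat(sprintf("  dispensations: %d\n", nrow(x$dispensations)))
  cat(sprintf("  hospital stays:%d\n", nrow(x$stays)))
  cat(sprintf("  LTD statuses:  %d\n", nrow(x$ltd_statuses)))
  cat(sprintf("  calendar:      %s .. %s (inclusion %s .. %s)\n",
              format(x$calendar$study_start), format(x$calendar$study_end),
              format(x$calendar$inclusion_start),
              format(x$calendar$inclusion_end)))
  invisible(x)
}

bundle_files <- c(patients = "patients.csv",
                  dispensations = "dispensations.csv",
                  stays = "hospital_stays.csv",
                  ltd_statuses = "ltd.csv")

parse_date_col <- function(x, file, col, required = TRUE) {
  x <- trimws(x)
  parsed <- as.Date(rep(NA_character_, length(x)))
  nonblank <- nzchar(x) & !is.na(x)
  idx_nb <- which(nonblank)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[idx_nb])
  val <- as.Date(x[idx_nb][ok], format = "%Y-%m-%d")
  bad_mask <- !ok
  bad_mask[ok][is.na(val)] <- TRUE
  bad <- idx_nb[bad_mask]
  if (required) bad <- sort(unique(c(bad, which(!nonblank))))
  if (length(bad)) {
    claims_abort(
      sprintf("%s: unparseable date in column '%s' at line %d", file, col,
              bad[1] + 1L),  # +1 for the header line
      "cllclaims_validation_error"
    )
  }
  parsed[idx_nb[ok]] <- val
  parsed
}

read_table_checked <- function(path, table) {
  if (!file.exists(path)) {
    claims_abort(sprintf("file not found: %s", path), "cllclaims_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, na.strings = NULL)
  missing <- setdiff(bundle_schema[[table]], names(df))
  if (length(missing)) {
    claims_abort(
      sprintf("%s: missing required column(s): %s", basename(path),
              paste(missing, collapse = ", ")),
      "cllclaims_schema_error"
    )
  }
  df[bundle_schema[[table]]]
}

#' Read a claims bundle from a directory of CSV files
#'
#' Expects `patients.csv`, `dispensations.csv`, `hospital_stays.csv` and
#' `ltd.csv` (UTF-8, ISO-8601 dates, ";"-separated multi-diagnosis fields)
#' with a strict header check.  The returned bundle is fully validated.
#'
#' @param dir directory containing the four files.
#' @param calendar a [study_calendar()].
#' @return a `"claims_bundle"`.
#' @export
read_bundle <- function(dir, calendar = study_calendar()) {
  f <- function(table) file.path(dir, bundle_files[[table]])

  pat <- read_table_checked(f("patients"), "patients")
  pat$death_date <- parse_date_col(pat$death_date, "patients.csv",
                                   "death_date", required = FALSE)
  cov <- toupper(trimws(pat$general_scheme_covered))
  if (nrow(pat) && !all(cov %in% c("TRUE", "FALSE"))) {
    claims_abort("patients.csv: general_scheme_covered must be TRUE/FALSE",
                 "cllclaims_validation_error")
  }
  pat$general_scheme_covered <- cov == "TRUE"

  disp <- read_table_checked(f("dispensations"), "dispensations")
  disp$date <- parse_date_col(disp$date, "dispensations.csv", "date")
  qty <- suppressWarnings(as.integer(disp$quantity))
  if (nrow(disp) && any(is.na(qty))) {
    claims_abort(
      sprintf("dispensations.csv: non-integer quantity at line %d",
              which(is.na(qty))[1] + 1L),
      "cllclaims_validation_error"
    )
  }
  disp$quantity <- qty

  stays <- read_table_checked(f("stays"), "stays")
  stays$admission_date <- parse_date_col(stays$admission_date,
                                         "hospital_stays.csv", "admission_date")
  stays$discharge_date <- parse_date_col(stays$discharge_date,
                                         "hospital_stays.csv", "discharge_date")

  ltd <- read_table_checked(f("ltd_statuses"), "ltd_statuses")
  ltd$start_date <- parse_date_col(ltd$start_date, "ltd.csv", "start_date")

  claims_bundle(pat, disp, stays, ltd, calendar = calendar)
}

#' Write a claims bundle to a directory of CSV files
#'
#' Inverse of [read_bundle()]: `read_bundle(write_bundle(b, dir))` reproduces
#' the bundle field-for-field.  Absent death dates are written as empty
#' fields, not sentinel values.
#'
#' @param bundle a validated `"claims_bundle"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  validate_bundle(bundle)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) claims_abort(sprintf("cannot create directory: %s", dir),
                          "cllclaims_io_error")
  }
  fmt <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  pat <- bundle$patients
  pat$death_date <- fmt(pat$death_date)
  pat$general_scheme_covered <- ifelse(pat$general_scheme_covered,
                                       "TRUE", "FALSE")
  disp <- bundle$dispensations
  disp$date <- fmt(disp$date)
  stays <- bundle$stays
  stays$admission_date <- fmt(stays$admission_date)
  stays$discharge_date <- fmt(stays$discharge_date)
  ltd <- bundle$ltd_statuses
  ltd$start_date <- fmt(ltd$start_date)

  out <- list(patients = pat, dispensations = disp, stays = stays,
              ltd_statuses = ltd)
  for (tab in names(out)) {
    path <- file.path(dir, bundle_files[[tab]])
    tryCatch(
      utils::write.csv(out[[tab]], path, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8"),
      error = function(e) claims_abort(
        sprintf("cannot write %s: %s", path, conditionMessage(e)),
        "cllclaims_io_error")
    )
  }
  invisible(dir)
}
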