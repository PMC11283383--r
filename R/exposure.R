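# Exposure module: ibrutinib regimen construction from pharmacy
# dispensations, line of treatment, cotherapy, next treatment and the
# treatment-free interval (TFI).
#
# Claims carry no dosage, so drug coverage is valued at the lowest posology
# used in practice (one capsule per day): a dispensation of q capsules on
# day d covers days d .. d+q-1.  A decrease in posology is thereby never
# mistaken for a discontinuation; the price is that short treatment pauses
# are invisible.

#' Default ATC code lists for the pipeline
#'
#' `cll_specific` holds the systemic treatments used in CLL other than
#' ibrutinib (they define prior lines, cotherapy and next treatments);
#' antihypertensive classes are ATC level-3 groups, antithrombotics ATC
#' level-4 prefixes.  `session_marker` is the opaque code standing for an
#' infusion session whose drug is bundled in the hospital tariff (intra-DRG)
#' and therefore invisible as a line item.
#'
#' @return a named list of code sets, class `"drug_code_list"`.
#' @export
default_drug_codes <- function() {
  structure(list(
    ibrutinib = "L01EL01",
    cll_specific = c(
      rituximab = "L01FA01", bendamustine = "L01AA09",
      fludarabine = "L01BB05", obinutuzumab = "L01FA03",
      chlorambucil = "L01AA02", venetoclax = "L01XX52",
      idelalisib = "L01EM01", acalabrutinib = "L01EL02",
      lenalidomide = "L04AX04", doxorubicin = "L01DB01",
      bortezomib = "L01XG01"
    ),
    antihypertensive_classes = c("C02", "C03", "C07", "C08", "C09"),
    anticoagulant = c("B01AA", "B01AB", "B01AE", "B01AF"),
    antiplatelet = "B01AC",
    session_marker = "SESSION",
    pacemaker = "PACEMAKER"
  ), class = "drug_code_list")
}

drug_label <- function(atc, codes) {
  lab <- names(codes$cll_specific)[match(atc, codes$cll_specific)]
  ifelse(is.na(lab), atc, lab)
}

#' Build ibrutinib regimens from dispensations
#'
#' Consecutive dispensations belong to the same regimen when the next
#' dispensation occurs no later than `grace_days` after the running coverage
#' end; a longer break closes the regimen and the next dispensation opens a
#' new one.  A regimen counts as permanently discontinued ("completed", in
#' the sense that its observation is complete) when its coverage ends at
#' least `discontinuation_days` before the end of follow-up, or when the
#' patient died under follow-up; a regimen still covering at the end of
#' follow-up is right-censored (`end_reason = "end_of_followup"`).
#'
#' @param dates `Date` vector of the patient's ibrutinib dispensation dates.
#' @param quantities integer vector of capsule counts, same length.
#' @param followup_end end of follow-up for the patient.
#' @param death_date death date or `NA`.
#' @param min_daily_units capsules per day used to value coverage (default
#'   1, the lowest posology in practice).
#' @param grace_days permissible refill delay beyond coverage end
#'   (default 30).
#' @param discontinuation_days break length after which a regimen end counts
#'   as permanent discontinuation (default 90).
#' @return data.frame with one row per regimen: `ordinal`, `start_date`,
#'   `coverage_end_date` (capped at `followup_end`), `n_dispensations`,
#'   `completed`, `end_reason`.
#' @export
build_regimens <- function(dates, quantities, followup_end, death_date = NA,
                           min_daily_units = 1L, grace_days = 30L,
                           discontinuation_days = 90L) {
  if (length(dates) != length(quantities)) {
    claims_abort("dates and quantities must have the same length",
                 "cllclaims_config_error")
  }
  o <- order(dates)
  dates <- dates[o]; quantities <- quantities[o]
  late <- dates > followup_end
  if (any(late)) {
    warning(sprintf("ignoring %d dispensation(s) after end of follow-up",
                    sum(late)))
    dates <- dates[!late]; quantities <- quantities[!late]
  }
  n <- length(dates)
  out <- data.frame(ordinal = integer(0), start_date = as.Date(character(0)),
                    coverage_end_date = as.Date(character(0)),
                    n_dispensations = integer(0), completed = logical(0),
                    end_reason = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  cover_days <- pmax(1L, as.integer(floor(quantities / min_daily_units)))
  starts <- integer(0); ends <- integer(0); counts <- integer(0)
  cur_start <- 1L
  cur_end <- as.numeric(dates[1]) + cover_days[1] - 1
  if (n > 1L) {
    for (i in 2:n) {
      # coverage intervals are half-open: a dispensation on the day after
      # the last covered day is contiguous, so the exclusive coverage end
      # (cur_end + 1) anchors the grace period
      if (as.numeric(dates[i]) <= cur_end + 1 + grace_days) {
        cur_end <- max(cur_end, as.numeric(dates[i]) + cover_days[i] - 1)
      } else {
        starts <- c(starts, cur_start); ends <- c(ends, cur_end)
        counts <- c(counts, i - 1L - sum(counts))
        cur_start <- i
        cur_end <- as.numeric(dates[i]) + cover_days[i] - 1
      }
    }
  }
  starts <- c(starts, cur_start); ends <- c(ends, cur_end)
  counts <- c(counts, n - sum(counts))

  died <- !is.na(death_date) && death_date <= followup_end
  k <- length(starts)
  cov_end_raw <- ends
  cov_end <- pmin(ends, as.numeric(followup_end))
  completed <- logical(k); reason <- character(k)
  for (j in seq_len(k)) {
    ongoing <- cov_end_raw[j] >= as.numeric(followup_end)
    if (ongoing) {
      completed[j] <- died
      reason[j] <- if (died) "death" else "end_of_followup"
    } else {
      completed[j] <- (cov_end_raw[j] + discontinuation_days <=
                         as.numeric(followup_end)) || died
      reason[j] <- if (completed[j]) "discontinuation" else "end_of_followup"
    }
  }
  data.frame(
    ordinal = seq_len(k),
    start_date = dates[starts],
    coverage_end_date = as.Date(cov_end, origin = "1970-01-01"),
    n_dispensations = counts,
    completed = completed,
    end_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Assign the line of treatment (L1 vs L2+)
#'
#' A patient is L2+ iff at least one CLL-specific treatment (dispensation or
#' infusion-session record of a drug in `codes$cll_specific`) is dated
#' strictly before the index date, anywhere in the available history.
#'
#' @param index_date index date.
#' @param dispensations the patient's dispensation rows (all drugs).
#' @param codes a [default_drug_codes()] list.
#' @return list with `line` (`"L1"` or `"L2plus"`),
#'   `first_cll_treatment_date` (`Date` or `NA`) and
#'   `years_since_first_treatment` (numeric or `NA`).
#' @export
assign_line <- function(index_date, dispensations, codes = default_drug_codes()) {
  prior <- dispensations[dispensations$atc_code %in% codes$cll_specific &
                           dispensations$date < index_date, , drop = FALSE]
  if (nrow(prior) == 0L) {
    return(list(line = "L1", first_cll_treatment_date = as.Date(NA_character_),
                years_since_first_treatment = NA_real_))
  }
  first <- min(prior$date)
  list(line = "L2plus", first_cll_treatment_date = first,
       years_since_first_treatment = as.numeric(index_date - first) / DAYS_PER_YEAR)
}

#' Detect cotherapy during a regimen
#'
#' CLL-specific treatments dispensed within the regimen's coverage interval
#' are cotherapies; a regimen with none is monotherapy.
#'
#' @param regimen one row of [build_regimens()] output.
#' @param dispensations the patient's dispensation rows.
#' @param codes a [default_drug_codes()] list.
#' @return data.frame `co_drug`, `initiation_date`,
#'   `days_from_regimen_start`, sorted by date (0 rows = monotherapy).
#' @export
detect_cotherapy <- function(regimen, dispensations,
                             codes = default_drug_codes()) {
  co <- dispensations[dispensations$atc_code %in% codes$cll_specific &
                        dispensations$date >= regimen$start_date &
                        dispensations$date <= regimen$coverage_end_date, ,
                      drop = FALSE]
  co <- co[order(co$date, co$atc_code, method = "radix"), , drop = FALSE]
  data.frame(
    co_drug = drug_label(co$atc_code, codes),
    initiation_date = co$date,
    days_from_regimen_start = as.numeric(co$date - regimen$start_date),
    stringsAsFactors = FALSE
  )
}

#' Find the next treatment after permanent ibrutinib discontinuation
#'
#' The earliest CLL-specific (non-ibrutinib) dispensation strictly after the
#' last regimen's coverage end and no later than the end of follow-up.
#' Same-day candidates share the date; all their labels are reported,
#' alphabetically.
#'
#' @param regimens [build_regimens()] output for the patient.
#' @param dispensations the patient's dispensation rows.
#' @param followup_end end of follow-up.
#' @param codes a [default_drug_codes()] list.
#' @return list with `date` (`Date` or `NA`) and `drugs` (character vector,
#'   empty if none).
#' @export
find_next_treatment <- function(regimens, dispensations, followup_end,
                                codes = default_drug_codes()) {
  if (nrow(regimens) == 0L) {
    return(list(date = as.Date(NA_character_), drugs = character(0)))
  }
  cov_end <- regimens$coverage_end_date[nrow(regimens)]
  cand <- dispensations[dispensations$atc_code %in% codes$cll_specific &
                          dispensations$date > cov_end &
                          dispensations$date <= followup_end, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(date = as.Date(NA_character_), drugs = character(0)))
  }
  d0 <- min(cand$date)
  drugs <- sort(unique(drug_label(cand$atc_code[cand$date == d0], codes)))
  list(date = d0, drugs = drugs)
}

#' Treatment-free interval
#'
#' Days between the end of the last ibrutinib regimen and the first
#' dispensation of the next treatment.
#'
#' @param coverage_end_date coverage end of the last regimen.
#' @param next_treatment_date date of the next treatment, or `NA`.
#' @return number of days (>= 0), or `NA` when there is no next treatment.
#' @export
compute_tfi <- function(coverage_end_date, next_treatment_date) {
  if (is.na(next_treatment_date)) return(NA_real_)
  tfi <- as.numeric(next_treatment_date - coverage_end_date)
  if (tfi < 0) {
    claims_abort("next treatment precedes regimen coverage end",
                 "cllclaims_consistency_error")
  }
  tfi
}
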