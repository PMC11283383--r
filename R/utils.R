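# Internal helpers shared across modules.

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a

claims_abort <- function(message, class) {
  stop(structure(
    class = c(class, "cllclaims_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Convert a duration in days to months
#'
#' Reported "months" use the mean Gregorian month of 30.4375 days.
#'
#' @param days numeric vector of durations in days.
#' @return numeric vector of durations in months.
#' @export
days_to_months <- function(days) days / DAYS_PER_MONTH

# Normalize ICD-10 codes: uppercase, strip dots and whitespace, so that
# "C91.1" and "c911" match the same prefixes.
norm_icd <- function(x) {
  gsub("[. ]", "", toupper(trimws(x)))
}

# TRUE for each element of `codes` that starts with any of `prefixes`
# (both already normalized).
match_any_prefix <- function(codes, prefixes) {
  if (length(codes) == 0L || length(prefixes) == 0L) {
    return(logical(length(codes)))
  }
  hit <- logical(length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

# Split a ";"-separated multi-code field into a character vector
# (empty string -> character(0)).
split_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

# All diagnosis codes carried by a set of hospital stay rows.
stay_codes <- function(stays, positions = c("all", "main_related")) {
  positions <- match.arg(positions)
  if (nrow(stays) == 0L) return(character(0))
  cols <- if (positions == "all") {
    c("main_dx", "related_dx", "associated_dx")
  } else {
    c("main_dx", "related_dx")
  }
  out <- character(0)
  for (col in cols) {
    v <- stays[[col]]
    v <- v[!is.na(v) & nzchar(v)]
    if (length(v)) out <- c(out, unlist(strsplit(v, ";", fixed = TRUE)))
  }
  norm_icd(out)
}

# Deterministic, locale-independent ordering of character keys.
radix_order <- function(...) order(..., method = "radix")

# Mean/SD/median/quartile summary used by the report blocks.
summary_block <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(list(n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_,
                q1 = NA_real_, q3 = NA_real_, min = NA_real_, max = NA_real_))
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 2))
  list(n = length(x), mean = mean(x), sd = stats::sd(x), median = q[2],
       q1 = q[1], q3 = q[3], min = min(x), max = max(x))
}

#' Age in whole years at a reference date
#'
#' Birth dates are only known to the month (claims granularity); age is
#' computed from the mid-month (day 15) of the birth month.
#'
#' @param birth_year_month character vector, "YYYY-MM".
#' @param ref_date a `Date` (or vector) at which age is evaluated.
#' @return integer vector of completed years.
#' @export
age_at_date <- function(birth_year_month, ref_date) {
  mid <- as.Date(paste0(birth_year_month, "-15"))
  as.integer(floor(as.numeric(ref_date - mid) / DAYS_PER_YEAR))
}
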