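# Comorbidity module: twelve-month lookback profiling, probabilistic
# cardiovascular markers, and the age-adjusted Charlson index under the
# Quan ICD-10 coding.
#
# Lookback convention: hospital diagnoses are restricted to admissions in
# the 365 days before the index date; LTD statuses count whenever they are
# active at index (an LTD is a standing status, not an event), i.e. when
# their start date is on or before the index date.

.codemap_cache <- new.env(parent = emptyenv())

#' Load the ICD-10 code map
#'
#' Reads the category-to-prefix map (descriptive comorbidity categories,
#' Quan Charlson categories with weights and hierarchy, safety-event
#' categories) from YAML.  The default map ships with the package and can be
#' replaced by an edited copy.
#'
#' @param path YAML file; default the map shipped under `extdata`.
#' @return a list with elements `comorbidity`, `charlson`, `hierarchy`,
#'   `safety_events`, all prefixes normalized.
#' @export
load_codemap <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.codemap_cache$map)) return(.codemap_cache$map)
  if (default) {
    path <- system.file("extdata", "comorbidity_codes.yaml",
                        package = "cllclaims")
  }
  if (!nzchar(path) || !file.exists(path)) {
    claims_abort(sprintf("code map not found: %s", path), "cllclaims_io_error")
  }
  raw <- yaml::read_yaml(path)
  for (sec in c("comorbidity", "safety_events")) {
    raw[[sec]] <- lapply(raw[[sec]], function(v) norm_icd(as.character(v)))
  }
  raw$charlson <- lapply(raw$charlson, function(cat) {
    list(weight = as.numeric(cat$weight),
         codes = norm_icd(as.character(cat$codes)))
  })
  map <- raw
  if (default) .codemap_cache$map <- map
  map
}

# Diagnosis codes visible in the lookback window: hospital stays admitted in
# [index - 365, index) plus LTD statuses active at index.
lookback_codes <- function(index_date, ltd, stays,
                           positions = c("all", "main_related")) {
  window_start <- index_date - 365L
  st <- stays[stays$admission_date >= window_start &
                stays$admission_date < index_date, , drop = FALSE]
  codes <- stay_codes(st, positions = match.arg(positions))
  if (nrow(ltd)) {
    active <- ltd$start_date <= index_date
    codes <- c(codes, norm_icd(ltd$icd10_code[active]))
  }
  unique(codes)
}

#' Probabilistic cardiovascular markers
#'
#' Non-diagnostic claims signals of cardiovascular disease: a pacemaker
#' device code on any pre-index hospital stay, or chronic antithrombotic
#' dispensing -- at least `marker_k` dispensations of an antiplatelet
#' (B01AC) or of an anticoagulant (B01AA/B01AB/B01AE/B01AF) drug class in
#' the 12 months before index.  The per-class threshold keeps one-off
#' perioperative use from flagging chronic disease.
#'
#' @param index_date index date.
#' @param stays,dispensations the patient's rows.
#' @param codes a [default_drug_codes()] list.
#' @param marker_k dispensing threshold per drug class (default 3).
#' @return list of logicals: `pacemaker`, `antithrombotic`, `marker`.
#' @export
cardiovascular_markers <- function(index_date, stays, dispensations,
                                   codes = default_drug_codes(),
                                   marker_k = 3L) {
  pre_stays <- stays[stays$admission_date < index_date, , drop = FALSE]
  pacer <- FALSE
  if (nrow(pre_stays)) {
    dev <- unlist(lapply(pre_stays$device_codes, split_codes))
    pacer <- any(toupper(dev) %in% toupper(codes$pacemaker))
  }
  lb <- dispensations[dispensations$date >= index_date - 365L &
                        dispensations$date < index_date, , drop = FALSE]
  n_ap <- sum(match_any_prefix(lb$atc_code, codes$antiplatelet))
  n_ac <- sum(match_any_prefix(lb$atc_code, codes$anticoagulant))
  antithrombotic <- n_ap >= marker_k || n_ac >= marker_k
  list(pacemaker = pacer, antithrombotic = antithrombotic,
       marker = pacer || antithrombotic)
}

#' Charlson comorbidity index (Quan ICD-10 coding)
#'
#' Sums the Quan weights over distinct Charlson categories found among the
#' supplied diagnosis codes, applying the hierarchy rules (a severe form
#' supersedes its mild counterpart), plus age points when `age_points` is
#' `TRUE`: +1 per decade from 50-59 up to +4 for 80 and over.
#'
#' @param diagnosis_codes character vector of (normalized or raw) ICD-10
#'   codes from the lookback window.
#' @param age age in years at index.
#' @param codemap a [load_codemap()] list.
#' @param age_points include the age adjustment (default `TRUE`).
#' @return integer score.
#' @export
charlson_index <- function(diagnosis_codes, age, codemap = load_codemap(),
                           age_points = TRUE) {
  codes <- norm_icd(diagnosis_codes)
  present <- vapply(codemap$charlson, function(cat) {
    any(match_any_prefix(codes, cat$codes))
  }, logical(1))
  for (severe in names(codemap$hierarchy)) {
    mild <- codemap$hierarchy[[severe]]
    if (isTRUE(present[severe])) present[mild] <- FALSE
  }
  score <- sum(vapply(codemap$charlson[present], `[[`, numeric(1), "weight"))
  if (age_points && !is.na(age)) {
    score <- score + max(0L, min(4L, (age %/% 10L) - 4L))
  }
  as.integer(score)
}

#' Baseline comorbidity profile
#'
#' Scans the 12-month lookback (hospital diagnoses, all positions by
#' default) and the LTD statuses active at index, sets one flag per
#' descriptive category, combines the cardiovascular subtypes with the
#' probabilistic markers, and computes the Charlson index.
#'
#' @param index_date index date.
#' @param ltd,stays,dispensations the patient's rows.
#' @param age age in years at index (for the Charlson age points).
#' @param codemap a [load_codemap()] list.
#' @param codes a [default_drug_codes()] list (for the drug markers).
#' @param marker_k antithrombotic dispensing threshold (default 3).
#' @param age_points include Charlson age adjustment (default `TRUE`).
#' @param positions hospital diagnosis positions scanned for comorbidities:
#'   `"all"` (default) or `"main_related"`.
#' @return one-row data.frame of flags plus `cv_marker`, `cv_marker_only`,
#'   `n_comorbidities` and `charlson`.
#' @export
comorbidity_profile <- function(index_date, ltd, stays, dispensations, age,
                                codemap = load_codemap(),
                                codes = default_drug_codes(),
                                marker_k = 3L, age_points = TRUE,
                                positions = "all") {
  found <- lookback_codes(index_date, ltd, stays, positions = positions)
  cats <- names(codemap$comorbidity)
  flags <- vapply(cats, function(cat) {
    any(match_any_prefix(found, codemap$comorbidity[[cat]]))
  }, logical(1))

  cv_sub <- grepl("^cardiovascular\\.", cats)
  cv_dx <- any(flags[cv_sub])
  mk <- cardiovascular_markers(index_date, stays, dispensations,
                               codes = codes, marker_k = marker_k)
  cv_marker_only <- mk$marker && !cv_dx

  top <- as.list(flags[!cv_sub])
  top$cardiovascular <- cv_dx || cv_marker_only
  prof <- c(top, as.list(flags[cv_sub]))
  prof$cv_marker <- mk$marker
  prof$cv_marker_only <- cv_marker_only
  prof$n_comorbidities <- sum(unlist(top))
  prof$charlson <- charlson_index(found, age, codemap = codemap,
                                  age_points = age_points)
  as.data.frame(prof, stringsAsFactors = FALSE)
}
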