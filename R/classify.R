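# Daily acuity classification
#
# Intervention tables are wide: one row per (patient_id, care_day) with one
# logical column per intervention in the rule set's vocabulary (missing
# columns are treated as all-FALSE). Classification is deterministic and
# auditable: every classified day records the id of the rule that matched.

# Evaluate one rule against a wide flag table; returns a logical vector.
rule_matches <- function(rule, flags) {
  n <- nrow(flags)
  get_col <- function(name) {
    if (name %in% names(flags)) {
      tidyr::replace_na(as.logical(flags[[name]]), FALSE)
    } else {
      rep(FALSE, n)
    }
  }
  hit <- rep(TRUE, n)
  for (f in rule$all_of) hit <- hit & get_col(f)
  if (length(rule$any_of)) {
    any_hit <- rep(FALSE, n)
    for (f in rule$any_of) any_hit <- any_hit | get_col(f)
    hit <- hit & any_hit
  }
  for (f in rule$none_of) hit <- hit & !get_col(f)
  hit
}

# Vectorised first-match classification over a wide flag table.
classify_flags <- function(flags, ruleset) {
  n <- nrow(flags)
  category <- rep(NA_character_, n)
  matched <- rep(NA_character_, n)
  for (rule in ruleset$rules) {
    open <- is.na(category)
    if (!any(open)) break
    hit <- open & rule_matches(rule, flags)
    category[hit] <- rule$category
    matched[hit] <- rule$id
  }
  category[is.na(category)] <- ruleset$default_category
  matched[is.na(matched)] <- "default"
  list(category = acuity_factor(category), matched_rule_id = matched)
}

#' Classify a single infant care-day
#'
#' Applies the ordered rule table to one day's intervention flags. The first
#' matching rule determines the category; a day matching no rule is special
#' care (the default category).
#'
#' @param record A list or one-row data frame with `patient_id`, `care_day`
#'   and logical intervention flags named after the rule set vocabulary.
#'   Alternatively a bare named logical vector of flags.
#' @param ruleset An `acuity_ruleset` from [load_ruleset()].
#' @return A one-row tibble: `patient_id`, `care_day`, `category`,
#'   `matched_rule_id`.
#' @export
#' @examples
#' rs <- default_ruleset(adapted = TRUE)
#' classify_day(c(parenteral_nutrition = TRUE), rs)$category # HDC
classify_day <- function(record, ruleset) {
  if (is.logical(record) && !is.null(names(record))) {
    record <- c(list(patient_id = NA_character_, care_day = as.Date(NA)),
                as.list(record))
  }
  record <- tibble::as_tibble(as.list(record))
  flag_cols <- setdiff(names(record), c("patient_id", "care_day"))
  unknown <- setdiff(flag_cols, ruleset$vocabulary)
  if (length(unknown)) {
    stop("unknown intervention flag(s): ", paste(unknown, collapse = ", "))
  }
  res <- classify_flags(record[flag_cols], ruleset)
  tibble::tibble(
    patient_id = record$patient_id %||% NA_character_,
    care_day = as.Date(record$care_day %||% NA),
    category = res$category,
    matched_rule_id = res$matched_rule_id
  )
}

#' Classify every admitted care-day of a cohort
#'
#' Derives the set of admitted care-days (07:00-anchored) from the admission
#' intervals, looks up each day's intervention record and classifies it. Days
#' an infant was admitted but for which no intervention record exists are
#' handled by `missing_policy`: `"sc"` (default) classifies them as special
#' care with a warning and a count in the attached run report, `"error"`
#' aborts. Intervention records for days outside any admission interval are
#' always an error.
#'
#' @param interventions Wide intervention table: `patient_id`, `care_day`,
#'   plus logical flag columns within the rule set vocabulary.
#' @param ruleset An `acuity_ruleset`.
#' @param admissions Admission table with `patient_id`, `admit_time`,
#'   `discharge_time` (and any other columns, ignored).
#' @param missing_policy `"sc"` or `"error"`.
#' @return A tibble with one row per admitted (patient, care-day):
#'   `patient_id`, `care_day`, `category`, `matched_rule_id`. The number of
#'   missing-record days is attached as attribute `n_missing_days`.
#' @export
classify_cohort <- function(interventions, ruleset, admissions,
                            missing_policy = c("sc", "error")) {
  missing_policy <- match.arg(missing_policy)
  interventions <- tibble::as_tibble(interventions)
  admissions <- tibble::as_tibble(admissions)

  flag_cols <- setdiff(names(interventions), c("patient_id", "care_day"))
  unknown <- setdiff(flag_cols, ruleset$vocabulary)
  if (length(unknown)) {
    stop("intervention table has flag(s) outside the rule set vocabulary: ",
         paste(unknown, collapse = ", "))
  }
  interventions$care_day <- as.Date(interventions$care_day)
  if (anyDuplicated(interventions[c("patient_id", "care_day")])) {
    stop("more than one intervention record for the same (patient, care-day)")
  }

  admitted <- admitted_care_days(admissions)
  if (nrow(admitted) == 0) {
    return(structure(
      tibble::tibble(patient_id = character(), care_day = as.Date(character()),
                     category = acuity_factor(character()),
                     matched_rule_id = character()),
      n_missing_days = 0L
    ))
  }

  orphan <- dplyr::anti_join(
    interventions[c("patient_id", "care_day")], admitted,
    by = c("patient_id", "care_day")
  )
  if (nrow(orphan) > 0) {
    stop("intervention record(s) outside any admission interval: ",
         paste(utils::head(paste0(orphan$patient_id, "/", orphan$care_day), 5),
               collapse = ", "),
         if (nrow(orphan) > 5) sprintf(" (and %d more)", nrow(orphan) - 5) else "")
  }

  joined <- dplyr::left_join(admitted, interventions,
                             by = c("patient_id", "care_day"))
  has_record <- if (length(flag_cols)) {
    !Reduce(`&`, lapply(flag_cols, function(f) is.na(joined[[f]])))
  } else {
    rep(FALSE, nrow(joined))
  }
  n_missing <- sum(!has_record)
  if (n_missing > 0) {
    if (missing_policy == "error") {
      bad <- joined[!has_record, c("patient_id", "care_day")]
      stop("admitted care-day(s) without an intervention record: ",
           paste(utils::head(paste0(bad$patient_id, "/", bad$care_day), 5),
                 collapse = ", "))
    }
    warning(n_missing, " admitted care-day(s) had no intervention record; ",
            "classified as SC (missing-day policy)")
  }

  res <- classify_flags(joined[flag_cols], ruleset)
  out <- tibble::tibble(
    patient_id = joined$patient_id,
    care_day = joined$care_day,
    category = res$category,
    matched_rule_id = res$matched_rule_id
  )
  # Missing rows carry no flags, so classify_flags already fell through to the
  # default; relabel the audit trail for transparency.
  out$category[!has_record] <- ruleset$default_category
  out$matched_rule_id[!has_record] <- "missing_day"
  attr(out, "n_missing_days") <- as.integer(n_missing)
  out
}

# One row per admitted (patient, care-day): every 07:00-anchored day whose
# [07:00, 07:00+24h) span intersects the admission interval [admit, discharge).
admitted_care_days <- function(admissions) {
  if (nrow(admissions) == 0) {
    return(tibble::tibble(patient_id = character(), care_day = as.Date(character())))
  }
  admit <- parse_timestamp(admissions$admit_time)
  discharge <- parse_timestamp(admissions$discharge_time)
  if (any(discharge <= admit)) stop("discharge_time must be after admit_time")
  first <- care_day(admit)
  last <- care_day(discharge - 1) # [start, end): a 07:00 discharge ends the prior day
  days <- purrr::map2(first, last, seq, by = "day")
  out <- tibble::tibble(
    patient_id = rep(admissions$patient_id, lengths(days)),
    care_day = as.Date(unlist(days), origin = "1970-01-01")
  )
  dplyr::distinct(out)
}
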