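# Unit-shift accounting
#
# Converts admissions + daily acuity + staff records into one ledger row per
# unit-shift window: infant-hours split by acuity category and clinical
# staff-hours split by staff category. Conventions:
#
#   * every interval is half-open [start, end);
#   * infant presence = admission interval minus declared home-leave
#     intervals; the category charged to a window is the acuity of the
#     07:00-anchored care-day containing it, which automatically books a
#     03:00 admission to the previous date's night shift;
#   * staff hours are window-truncated clinical hours; nonclinical activity
#     (education, administration, introduction, students) is excluded
#     entirely; agency staff count exactly like employed staff;
#   * coordinator hours accumulate in their own column and never enter the
#     bedside staff-hour columns;
#   * staff crossing 07:00 are split across care-days by the window grid, so
#     night hours land on the date the night window starts.

# --- interval helpers -------------------------------------------------------

# Subtract a set of sub-intervals from [start, end); all half-open, numeric
# seconds. Returns a two-column matrix of kept pieces.
subtract_intervals <- function(start, end, sub_start, sub_end) {
  keep_s <- numeric()
  keep_e <- numeric()
  if (length(sub_start)) {
    ord <- order(sub_start)
    sub_start <- pmax(sub_start[ord], start)
    sub_end <- pmin(sub_end[ord], end)
    ok <- sub_end > sub_start
    sub_start <- sub_start[ok]; sub_end <- sub_end[ok]
    # merge overlapping subtrahends
    if (length(sub_start) > 1) {
      merged_s <- sub_start[1]; merged_e <- sub_end[1]
      for (i in seq_along(sub_start)[-1]) {
        if (sub_start[i] <= merged_e[length(merged_e)]) {
          merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], sub_end[i])
        } else {
          merged_s <- c(merged_s, sub_start[i]); merged_e <- c(merged_e, sub_end[i])
        }
      }
      sub_start <- merged_s; sub_end <- merged_e
    }
  }
  cursor <- start
  for (i in seq_along(sub_start)) {
    if (sub_start[i] > cursor) {
      keep_s <- c(keep_s, cursor); keep_e <- c(keep_e, sub_start[i])
    }
    cursor <- max(cursor, sub_end[i])
  }
  if (cursor < end) {
    keep_s <- c(keep_s, cursor); keep_e <- c(keep_e, end)
  }
  cbind(start = keep_s, end = keep_e)
}

# Expand admissions into presence intervals (admission minus home leaves).
presence_intervals <- function(admissions, home_leaves = NULL) {
  admissions <- tibble::as_tibble(admissions)
  if (nrow(admissions) == 0) {
    return(tibble::tibble(admission_id = character(), unit_id = character(),
                          patient_id = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC")))
  }
  if (!"admission_id" %in% names(admissions)) {
    admissions$admission_id <- paste0("adm", seq_len(nrow(admissions)))
  }
  admit <- as.numeric(parse_timestamp(admissions$admit_time))
  discharge <- as.numeric(parse_timestamp(admissions$discharge_time))
  if (any(discharge <= admit)) stop("discharge_time must be after admit_time")

  leaves <- normalize_home_leaves(admissions, home_leaves)
  pieces <- purrr::map(seq_len(nrow(admissions)), function(i) {
    lv <- leaves[leaves$admission_id == admissions$admission_id[i], , drop = FALSE]
    kept <- subtract_intervals(admit[i], discharge[i], lv$start, lv$end)
    tibble::tibble(admission_id = admissions$admission_id[i],
                   unit_id = admissions$unit_id[i],
                   patient_id = admissions$patient_id[i],
                   start = kept[, "start"], end = kept[, "end"])
  })
  out <- dplyr::bind_rows(pieces)
  out$start <- as.POSIXct(out$start, origin = "1970-01-01", tz = "UTC")
  out$end <- as.POSIXct(out$end, origin = "1970-01-01", tz = "UTC")
  out
}

# Accept leaves either as a separate table (admission_id, leave_start,
# leave_end) or as optional home_leave_start/home_leave_end columns on the
# admission table itself.
normalize_home_leaves <- function(admissions, home_leaves) {
  if (is.null(home_leaves) &&
      all(c("home_leave_start", "home_leave_end") %in% names(admissions))) {
    home_leaves <- admissions[!is.na(admissions$home_leave_start),
                              c("admission_id", "home_leave_start", "home_leave_end")]
    names(home_leaves) <- c("admission_id", "leave_start", "leave_end")
  }
  if (is.null(home_leaves) || nrow(home_leaves) == 0) {
    return(tibble::tibble(admission_id = character(), start = numeric(),
                          end = numeric()))
  }
  tibble::tibble(
    admission_id = home_leaves$admission_id,
    start = as.numeric(parse_timestamp(home_leaves$leave_start)),
    end = as.numeric(parse_timestamp(home_leaves$leave_end))
  )
}

# --- infant side ------------------------------------------------------------

#' Apportion infant presence to shift windows
#'
#' Splits every presence interval (admission minus home leave) across the
#' overlapping shift windows and charges each piece with the acuity category
#' of the care-day containing the window. Contributions sum exactly to total
#' in-unit presence hours over windows that cover the full presence span.
#'
#' @param admissions Admission table: `admission_id` (optional), `unit_id`,
#'   `patient_id`, `admit_time`, `discharge_time`, optional
#'   `home_leave_start`/`home_leave_end`.
#' @param acuity Acuity table from [classify_cohort()] (or generator ground
#'   truth): `patient_id`, `care_day`, `category`.
#' @param windows Window grid from [build_windows()].
#' @param home_leaves Optional separate leave table: `admission_id`,
#'   `leave_start`, `leave_end`.
#' @return Tibble of per-window, per-patient contributions: `unit_id`, `date`,
#'   `shift_type`, `patient_id`, `category`, `hours`.
#' @export
attribute_presence <- function(admissions, acuity, windows, home_leaves = NULL) {
  presence <- presence_intervals(admissions, home_leaves)
  windows <- tibble::as_tibble(windows)
  if (nrow(presence) == 0 || nrow(windows) == 0) {
    return(tibble::tibble(unit_id = character(), date = as.Date(character()),
                          shift_type = shift_factor(character()),
                          patient_id = character(),
                          category = acuity_factor(character()),
                          hours = numeric()))
  }
  hits <- dplyr::inner_join(presence,
                            windows[c("unit_id", "date", "shift_type",
                                      "window_start", "window_end")],
                            by = "unit_id", relationship = "many-to-many")
  hits <- dplyr::filter(hits, .data$start < .data$window_end,
                        .data$end > .data$window_start)
  hits$hours <- overlap_hours(hits$start, hits$end,
                              hits$window_start, hits$window_end)
  hits <- hits[hits$hours > 0, ]

  acuity <- tibble::as_tibble(acuity)
  acuity$care_day <- as.Date(acuity$care_day)
  hits <- dplyr::left_join(
    hits, acuity[c("patient_id", "care_day", "category")],
    by = c(patient_id = "patient_id", date = "care_day")
  )
  if (anyNA(hits$category)) {
    bad <- dplyr::distinct(hits[is.na(hits$category), c("patient_id", "date")])
    stop("presence without an acuity category for: ",
         paste(utils::head(paste0(bad$patient_id, "/", bad$date), 5),
               collapse = ", "),
         if (nrow(bad) > 5) sprintf(" (and %d more)", nrow(bad) - 5) else "")
  }
  hits$category <- acuity_factor(hits$category)
  dplyr::summarise(
    dplyr::group_by(hits, .data$unit_id, .data$date, .data$shift_type,
                    .data$patient_id, .data$category),
    hours = sum(.data$hours), .groups = "drop"
  )
}

# --- staff side -------------------------------------------------------------

# Merge overlapping records of the same person/unit/category/activity by
# interval union; double-counting one person is never physically meaningful.
merge_duplicate_staff <- function(staffing) {
  key <- c("person_id", "unit_id", "category", "activity")
  staffing <- dplyr::arrange(staffing, dplyr::across(dplyr::all_of(c(key, "start_num"))))
  grp <- dplyr::group_by(staffing, dplyr::across(dplyr::all_of(key)))
  merged <- dplyr::reframe(grp, {
    s <- .data$start_num; e <- .data$end_num; ag <- .data$agency
    out_s <- s[1]; out_e <- e[1]; out_a <- ag[1]
    if (length(s) > 1) {
      for (i in 2:length(s)) {
        j <- length(out_s)
        if (s[i] < out_e[j]) {
          out_e[j] <- max(out_e[j], e[i])
          out_a[j] <- out_a[j] | ag[i]
        } else {
          out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i]); out_a <- c(out_a, ag[i])
        }
      }
    }
    tibble::tibble(start_num = out_s, end_num = out_e, agency = out_a)
  })
  n_merged <- nrow(staffing) - nrow(merged)
  if (n_merged > 0) {
    warning(n_merged, " overlapping duplicate staff record(s) merged by interval union")
  }
  merged
}

#' Build per-unit-shift ledgers
#'
#' Produces one ledger row per shift window with infant-hours by acuity
#' category and clinical staff-hours by staff category. Nonclinical staff
#' records are dropped, coordinator hours are accumulated separately, agency
#' records are included identically to employed staff, and overlapping
#' duplicate records for one person are merged with a warning.
#'
#' @inheritParams attribute_presence
#' @param staffing Staff table: `person_id`, `unit_id`, `category` (one of
#'   RN, RN_specialist, nursing_assistant, coordinator), `start_time`,
#'   `end_time`, `activity` (clinical/nonclinical), `agency` (logical).
#' @return Tibble with one row per window: `unit_id`, `date`, `shift_type`,
#'   `weekend`, `duration`, `ic_hours`, `hdc_hours`, `sc_hours`, `rn_hours`,
#'   `rn_spec_hours`, `na_hours`, `coordinator_hours`, `coordinator_present`.
#' @export
build_ledgers <- function(admissions, acuity, staffing, windows,
                          home_leaves = NULL) {
  windows <- tibble::as_tibble(windows)
  staffing <- tibble::as_tibble(staffing)

  # infant side
  contrib <- attribute_presence(admissions, acuity, windows, home_leaves)
  infant <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(contrib, .data$unit_id, .data$date, .data$shift_type,
                      .data$category),
      hours = sum(.data$hours), .groups = "drop"
    ),
    names_from = "category", values_from = "hours", values_fill = 0,
    names_expand = TRUE
  )
  for (cat in ACUITY_LEVELS) if (!cat %in% names(infant)) infant[[cat]] <- numeric(nrow(infant))

  # staff side
  staff_cols <- c(RN = "rn_hours", RN_specialist = "rn_spec_hours",
                  nursing_assistant = "na_hours", coordinator = "coordinator_hours")
  if (nrow(staffing) > 0) {
    bad_cat <- setdiff(unique(as.character(staffing$category)), STAFF_CATEGORIES)
    if (length(bad_cat)) {
      stop("unknown staff categor(ies): ", paste(bad_cat, collapse = ", "))
    }
    bad_unit <- setdiff(unique(staffing$unit_id), unique(windows$unit_id))
    if (length(bad_unit)) {
      stop("staff record(s) for unknown unit(s): ", paste(bad_unit, collapse = ", "))
    }
    staffing$start_num <- as.numeric(parse_timestamp(staffing$start_time))
    staffing$end_num <- as.numeric(parse_timestamp(staffing$end_time))
    if (any(staffing$end_num <= staffing$start_num)) {
      stop("staff record end_time must be after start_time")
    }
    raw_h <- (staffing$end_num - staffing$start_num) / 3600
    if (any(raw_h > 24)) stop("staff record longer than 24 h")
    if (!"agency" %in% names(staffing)) staffing$agency <- FALSE
    clinical <- staffing[staffing$activity == "clinical", ]
    clinical <- merge_duplicate_staff(clinical)

    hits <- dplyr::inner_join(clinical,
                              windows[c("unit_id", "date", "shift_type",
                                        "window_start", "window_end")],
                              by = "unit_id", relationship = "many-to-many")
    hits <- dplyr::filter(hits,
                          .data$start_num < as.numeric(.data$window_end),
                          .data$end_num > as.numeric(.data$window_start))
    hits$hours <- pmax(0, pmin(hits$end_num, as.numeric(hits$window_end)) -
                          pmax(hits$start_num, as.numeric(hits$window_start))) / 3600
    staff <- tidyr::pivot_wider(
      dplyr::summarise(
        dplyr::group_by(hits, .data$unit_id, .data$date, .data$shift_type,
                        .data$category),
        hours = sum(.data$hours), .groups = "drop"
      ),
      names_from = "category", values_from = "hours", values_fill = 0
    )
  } else {
    staff <- tibble::tibble(unit_id = character(), date = as.Date(character()),
                            shift_type = shift_factor(character()))
  }
  for (cat in names(staff_cols)) {
    if (!cat %in% names(staff)) staff[[cat]] <- numeric(nrow(staff))
  }

  ledgers <- dplyr::left_join(
    windows[c("unit_id", "date", "shift_type", "weekend", "duration")],
    infant, by = c("unit_id", "date", "shift_type")
  )
  ledgers <- dplyr::left_join(ledgers, staff,
                              by = c("unit_id", "date", "shift_type"))
  out <- dplyr::mutate(ledgers,
    ic_hours = tidyr::replace_na(.data$IC, 0),
    hdc_hours = tidyr::replace_na(.data$HDC, 0),
    sc_hours = tidyr::replace_na(.data$SC, 0),
    rn_hours = tidyr::replace_na(.data$RN, 0),
    rn_spec_hours = tidyr::replace_na(.data$RN_specialist, 0),
    na_hours = tidyr::replace_na(.data$nursing_assistant, 0),
    coordinator_hours = tidyr::replace_na(.data$coordinator, 0),
    coordinator_present = .data$coordinator_hours > 0
  )
  dplyr::select(out, "unit_id", "date", "shift_type", "weekend", "duration",
                "ic_hours", "hdc_hours", "sc_hours", "rn_hours",
                "rn_spec_hours", "na_hours", "coordinator_hours",
                "coordinator_present")
}
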