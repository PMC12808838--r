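# Synthetic roster generator
#
# Builds a staff-shift table calibrated against a demand table of recommended
# RN hours per unit-shift. Clinical RN + specialist-RN hours falling inside
# each analysis window equal target_ratio x recommended hours (optionally
# with between-shift dispersion), up to one 0.25 h scheduling quantum;
# nursing-assistant hours fill the complement dictated by the skill mix.
# Records are aligned to the analysis windows — 7 h day/evening blocks, 10 h
# night blocks, merged 14 h day+evening shifts and sub-shift remainder
# records — because the provision ratio is defined on windowed hours: any
# spill past a window boundary would be charged to the neighbouring shift and
# break the calibration identity.
#
# Quantized hours are rounded UP to the next quantum, so a roster calibrated
# at target 1.0 never dips below the recommendation through rounding alone.

SCHED_QUANTUM <- 0.25 # hours; real rosters are quarter-hour granular

quantize_up <- function(hours) ceiling(hours / SCHED_QUANTUM - 1e-9) * SCHED_QUANTUM
quantize_near <- function(hours) round(hours / SCHED_QUANTUM) * SCHED_QUANTUM

#' Roster generator parameters
#'
#' Defaults emulate the staffing climate the benchmark is designed to
#' measure: a target provision ratio of 0.76 with between-shift SD 0.22
#' (approximately an interquartile range of 0.30), RN share of nursing-staff
#' hours 46.5%, specialist share of RN hours 61/73/80% on day/evening/night
#' shifts, coordinators present on 85.4% of day shifts, 1.2% of evening
#' shifts and never at night, and small fractions of nonclinical and agency
#' records.
#'
#' @param target_ratio Intended provision ratio per shift (> 0).
#' @param ratio_sd Between-shift SD of the intended ratio (0 = exact
#'   calibration on every shift).
#' @param skill_mix_rn_fraction Fraction of nursing-staff hours provided by
#'   RNs (incl. specialists).
#' @param skill_mix_sd Between-shift SD of the RN fraction.
#' @param specialist_share Fraction of RN hours from specialist RNs; scalar
#'   or named per-shift-type vector (`day`, `evening`, `night`).
#' @param specialist_share_sd Between-shift SD of the specialist share.
#' @param shift_length_range Allowed staffing shift durations in hours;
#'   must lie within \[4, 15\].
#' @param nonclinical_fraction Fraction of (additional) records flagged
#'   nonclinical.
#' @param coordinator_day_prob,coordinator_evening_prob,coordinator_night_prob
#'   Probability that a shift of each type has a designated coordinator.
#' @param agency_fraction Fraction of clinical records flagged as agency.
#' @param weekend_day_ratio_delta Additive shift of the target ratio on
#'   weekend day shifts (0 = no weekday/weekend effect).
#' @param seed Integer RNG seed.
#' @return Validated object of class `roster_params`.
#' @export
roster_params <- function(target_ratio = 0.76,
                          ratio_sd = 0.22,
                          skill_mix_rn_fraction = 0.465,
                          skill_mix_sd = 0.08,
                          specialist_share = c(day = 0.61, evening = 0.73,
                                               night = 0.80),
                          specialist_share_sd = 0.08,
                          shift_length_range = c(4, 15),
                          nonclinical_fraction = 0.05,
                          coordinator_day_prob = 0.854,
                          coordinator_evening_prob = 0.012,
                          coordinator_night_prob = 0,
                          agency_fraction = 0.05,
                          weekend_day_ratio_delta = 0,
                          seed = 1L) {
  if (target_ratio <= 0) stop("target_ratio must be > 0")
  fracs <- c(skill_mix_rn_fraction, specialist_share, nonclinical_fraction,
             coordinator_day_prob, coordinator_evening_prob,
             coordinator_night_prob, agency_fraction)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("all fractions and probabilities must lie in [0, 1]")
  }
  if (length(shift_length_range) != 2 || shift_length_range[1] < 4 ||
      shift_length_range[2] > 15 || shift_length_range[1] > shift_length_range[2]) {
    stop("shift_length_range must be an increasing pair within [4, 15]")
  }
  if (length(specialist_share) == 1) {
    specialist_share <- setNames(rep(specialist_share, 3), SHIFT_LEVELS)
  }
  if (!all(SHIFT_LEVELS %in% names(specialist_share))) {
    stop("specialist_share must be a scalar or named day/evening/night vector")
  }
  structure(
    list(target_ratio = target_ratio, ratio_sd = ratio_sd,
         skill_mix_rn_fraction = skill_mix_rn_fraction,
         skill_mix_sd = skill_mix_sd,
         specialist_share = specialist_share[SHIFT_LEVELS],
         specialist_share_sd = specialist_share_sd,
         shift_length_range = as.numeric(shift_length_range),
         nonclinical_fraction = nonclinical_fraction,
         coordinator_probs = c(day = coordinator_day_prob,
                               evening = coordinator_evening_prob,
                               night = coordinator_night_prob),
         agency_fraction = agency_fraction,
         weekend_day_ratio_delta = weekend_day_ratio_delta,
         seed = as.integer(seed)),
    class = "roster_params"
  )
}

#' Generate a calibrated staff roster
#'
#' @param params A `roster_params` object.
#' @param benchmark_demand Demand table with one row per unit-shift:
#'   `unit_id`, `date`, `shift_type`, `recommended_rn_hours`.
#' @param seed RNG seed (defaults to `params$seed`).
#' @param windows Optional window grid; when given, `benchmark_demand` must
#'   cover every window or an error names the first missing unit-shift.
#' @return List with `staffing` (the staff-shift table) and
#'   `ground_truth_ratio` (`unit_id`, `date`, `shift_type`,
#'   `intended_ratio`).
#' @export
generate_roster <- function(params, benchmark_demand, seed = NULL,
                            windows = NULL) {
  stopifnot(inherits(params, "roster_params"))
  demand <- tibble::as_tibble(benchmark_demand)
  need <- c("unit_id", "date", "shift_type", "recommended_rn_hours")
  missing_cols <- setdiff(need, names(demand))
  if (length(missing_cols)) {
    stop("demand table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(windows)) {
    uncovered <- dplyr::anti_join(
      tibble::as_tibble(windows)[c("unit_id", "date", "shift_type")],
      demand, by = c("unit_id", "date", "shift_type")
    )
    if (nrow(uncovered) > 0) {
      stop("demand table missing unit-shift(s) present in the simulation window: ",
           paste0(uncovered$unit_id[1], " ", uncovered$date[1], " ",
                  uncovered$shift_type[1]),
           if (nrow(uncovered) > 1) sprintf(" (and %d more)", nrow(uncovered) - 1) else "")
    }
  }
  withr::with_seed(seed %||% params$seed,
                   generate_roster_impl(params, demand))
}

generate_roster_impl <- function(params, demand) {
  demand <- dplyr::arrange(demand, .data$unit_id, .data$date, .data$shift_type)
  n <- nrow(demand)
  shift <- as.character(demand$shift_type)
  duration <- unname(SHIFT_DURATIONS[shift])
  weekend <- is_weekend(demand$date)

  # intended ratio per shift (dispersion + optional weekend day-shift effect)
  target <- params$target_ratio +
    ifelse(weekend & shift == "day", params$weekend_day_ratio_delta, 0)
  intended <- if (params$ratio_sd > 0) {
    pmax(0.05, stats::rnorm(n, target, params$ratio_sd))
  } else {
    target
  }

  rec <- demand$recommended_rn_hours
  rn_total <- ifelse(rec > 0, quantize_up(intended * rec), duration) # empty shift: 1 baseline RN
  realized_intended <- ifelse(rec > 0, rn_total / rec, NA_real_)

  spec_share <- unname(params$specialist_share[shift])
  if (params$specialist_share_sd > 0) {
    spec_share <- pmin(1, pmax(0, stats::rnorm(n, spec_share,
                                               params$specialist_share_sd)))
  }
  spec_hours <- pmin(rn_total, quantize_near(spec_share * rn_total))
  rn_hours <- rn_total - spec_hours

  f <- params$skill_mix_rn_fraction
  f <- if (params$skill_mix_sd > 0) {
    pmin(0.95, pmax(0.15, stats::rnorm(n, f, params$skill_mix_sd)))
  } else {
    rep(f, n)
  }
  na_hours <- ifelse(f >= 0.999, 0, quantize_near(rn_total * (1 - f) / f))

  coord <- stats::runif(n) < params$coordinator_probs[shift]

  win_start <- as.POSIXct(paste(format(demand$date), "00:00:00"), tz = "UTC") +
    unname(SHIFT_OFFSETS[shift]) * 3600

  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    pieces <- list(
      decompose_hours(rn_hours[i], "RN", win_start[i], duration[i]),
      decompose_hours(spec_hours[i], "RN_specialist", win_start[i], duration[i]),
      decompose_hours(na_hours[i], "nursing_assistant", win_start[i], duration[i])
    )
    if (coord[i]) {
      pieces <- c(pieces, list(tibble::tibble(
        category = "coordinator", start_time = win_start[i],
        end_time = win_start[i] + duration[i] * 3600
      )))
    }
    rows <- dplyr::bind_rows(pieces)
    if (nrow(rows)) {
      rows$unit_id <- demand$unit_id[i]
      rows$row_id <- i
    }
    rec_list[[i]] <- rows
  }
  staffing <- dplyr::bind_rows(rec_list)
  if (nrow(staffing) == 0) {
    staffing <- tibble::tibble(category = character(),
                               start_time = as.POSIXct(character(), tz = "UTC"),
                               end_time = as.POSIXct(character(), tz = "UTC"),
                               unit_id = character(), row_id = integer())
  }
  staffing$activity <- "clinical"

  # merge day + evening full blocks into 14 h shifts for a share of staff
  staffing <- merge_long_shifts(staffing)

  # extra nonclinical records (education/administration), excluded downstream
  n_nc <- round(params$nonclinical_fraction * nrow(staffing))
  if (n_nc > 0) {
    pick <- sample.int(nrow(staffing), n_nc, replace = TRUE)
    nc <- staffing[pick, ]
    nc$activity <- "nonclinical"
    nc$end_time <- nc$start_time + pmin(4, interval_hours(nc$start_time, nc$end_time)) * 3600
    staffing <- dplyr::bind_rows(staffing, nc)
  }

  staffing$agency <- stats::runif(nrow(staffing)) < params$agency_fraction
  staffing$person_id <- sprintf("%s_p%05d", staffing$unit_id,
                                stats::ave(seq_len(nrow(staffing)),
                                           staffing$unit_id, FUN = seq_along))
  staffing <- dplyr::select(
    tibble::as_tibble(staffing),
    "person_id", "unit_id", "category", "start_time", "end_time",
    "activity", "agency"
  )

  list(
    staffing = staffing,
    ground_truth_ratio = tibble::tibble(
      unit_id = demand$unit_id, date = demand$date,
      shift_type = shift_factor(shift), intended_ratio = realized_intended
    )
  )
}

# Split a quantized hour total into window-aligned records: full-window
# blocks plus at most one sub-shift remainder.
decompose_hours <- function(hours, category, win_start, duration) {
  if (hours <= 0) {
    return(tibble::tibble(category = character(),
                          start_time = as.POSIXct(character(), tz = "UTC"),
                          end_time = as.POSIXct(character(), tz = "UTC")))
  }
  n_full <- floor(hours / duration + 1e-9)
  rem <- hours - n_full * duration
  starts <- rep(win_start, n_full)
  ends <- rep(win_start + duration * 3600, n_full)
  if (rem > 1e-9) {
    starts <- c(starts, win_start)
    ends <- c(ends, win_start + rem * 3600)
  }
  tibble::tibble(category = category, start_time = starts, end_time = ends)
}

# Pair one full day block with one full evening block of the same unit/date/
# category into a single 07:00-21:00 record, mimicking long combined shifts.
merge_long_shifts <- function(staffing) {
  if (nrow(staffing) == 0) return(staffing)
  hms <- format(staffing$start_time, "%H:%M:%S", tz = "UTC")
  len <- interval_hours(staffing$start_time, staffing$end_time)
  day_full <- which(hms == "07:00:00" & abs(len - 7) < 1e-9 &
                      staffing$category != "coordinator")
  eve_full <- which(hms == "14:00:00" & abs(len - 7) < 1e-9 &
                      staffing$category != "coordinator")
  if (!length(day_full) || !length(eve_full)) return(staffing)
  key <- function(idx) paste(staffing$unit_id[idx],
                             as.Date(staffing$start_time[idx], tz = "UTC"),
                             staffing$category[idx])
  matched <- match(key(day_full), key(eve_full))
  usable <- which(!is.na(matched) & !duplicated(matched))
  if (!length(usable)) return(staffing)
  d_idx <- day_full[usable]
  e_idx <- eve_full[matched[usable]]
  staffing$end_time[d_idx] <- staffing$end_time[e_idx]
  staffing[-e_idx, ]
}
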