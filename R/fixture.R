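# Fixture bundles
#
# A simulation run is persisted as five CSV tables plus a YAML manifest
# (schema version, seeds, full generator parameters). Timestamps are written
# as timezone-naive local "YYYY-MM-DD HH:MM:SS"; the round trip is lossless
# and regeneration from the manifest reproduces the tables bit for bit.

FIXTURE_SCHEMA_VERSION <- 1L

FIXTURE_FILES <- c(admissions = "admissions.csv",
                   interventions = "interventions.csv",
                   staffing = "staffing.csv",
                   ground_truth_acuity = "ground_truth_acuity.csv",
                   ground_truth_ratio = "ground_truth_ratio.csv")

#' Simulate a full study: cohort, windows, demand and calibrated roster
#'
#' Runs the cohort generator, derives the recommended RN hours per unit-shift
#' from the ground-truth acuity over the simulated window grid, and generates
#' a roster calibrated against that demand. This is the one-call entry point
#' for producing a complete synthetic data set with known ground truth.
#'
#' @param cohort A `cohort_params` object.
#' @param roster A `roster_params` object.
#' @return A fixture bundle: `admissions`, `interventions`, `staffing`,
#'   `ground_truth_acuity`, `ground_truth_ratio`, `windows`, `cohort_params`,
#'   `roster_params`.
#' @export
simulate_study <- function(cohort = cohort_params(), roster = roster_params()) {
  cohort_out <- generate_cohort(cohort)
  windows <- build_windows(cohort$start_date,
                           cohort$start_date + cohort$n_weeks * 7 - 1,
                           names(cohort$unit_profiles))
  contrib <- attribute_presence(cohort_out$admissions,
                                cohort_out$ground_truth_acuity, windows)
  infant <- dplyr::summarise(
    dplyr::group_by(contrib, .data$unit_id, .data$date, .data$shift_type,
                    .data$category),
    hours = sum(.data$hours), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(infant, names_from = "category",
                             values_from = "hours", values_fill = 0,
                             names_expand = TRUE)
  for (cat in ACUITY_LEVELS) if (!cat %in% names(wide)) wide[[cat]] <- 0
  demand <- dplyr::left_join(windows[c("unit_id", "date", "shift_type")],
                             wide, by = c("unit_id", "date", "shift_type"))
  demand[ACUITY_LEVELS] <- lapply(demand[ACUITY_LEVELS],
                                  function(x) tidyr::replace_na(x, 0))
  demand$recommended_rn_hours <- recommended_rn_hours(
    tibble::tibble(IC = demand$IC, HDC = demand$HDC, SC = demand$SC)
  )
  roster_out <- generate_roster(roster, demand, windows = windows)
  list(admissions = cohort_out$admissions,
       interventions = cohort_out$interventions,
       staffing = roster_out$staffing,
       ground_truth_acuity = cohort_out$ground_truth_acuity,
       ground_truth_ratio = roster_out$ground_truth_ratio,
       windows = windows,
       cohort_params = cohort, roster_params = roster)
}

#' Write a fixture bundle to a directory
#'
#' Writes the five CSV tables and `manifest.yaml`. The target directory must
#' already exist; nothing is written if it does not (no partial file sets).
#'
#' @param bundle A bundle from [simulate_study()].
#' @param dir Existing output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  tables <- lapply(FIXTURE_FILES, function(f) NULL)
  for (nm in names(FIXTURE_FILES)) {
    tab <- bundle[[nm]]
    for (col in names(tab)) {
      if (inherits(tab[[col]], "POSIXct")) tab[[col]] <- format_timestamp(tab[[col]])
    }
    tables[[nm]] <- tab
  }
  manifest <- list(
    schema_version = FIXTURE_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("acuitybench")),
    cohort_params = params_to_list(bundle$cohort_params),
    roster_params = params_to_list(bundle$roster_params),
    table_hashes = lapply(tables, rlang::hash)
  )
  for (nm in names(FIXTURE_FILES)) {
    readr::write_csv(tables[[nm]], file.path(dir, FIXTURE_FILES[[nm]]), na = "")
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a fixture bundle back from a directory
#'
#' @param dir Directory written by [write_fixture()].
#' @return The bundle (tables plus reconstructed parameter objects).
#' @export
read_fixture <- function(dir) {
  manifest_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(manifest_path)) stop("no manifest.yaml in ", dir)
  manifest <- yaml::read_yaml(manifest_path)
  ts <- function(x) parse_timestamp(x)
  adm <- readr::read_csv(file.path(dir, "admissions.csv"),
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  admissions <- tibble::tibble(
    admission_id = adm$admission_id, unit_id = adm$unit_id,
    patient_id = adm$patient_id,
    admit_time = ts(adm$admit_time), discharge_time = ts(adm$discharge_time),
    ga_stratum = adm$ga_stratum, los_days = as.integer(adm$los_days),
    home_leave_start = ts(ifelse(adm$home_leave_start == "" | is.na(adm$home_leave_start),
                                 NA, adm$home_leave_start)),
    home_leave_end = ts(ifelse(adm$home_leave_end == "" | is.na(adm$home_leave_end),
                               NA, adm$home_leave_end))
  )
  iv <- readr::read_csv(file.path(dir, "interventions.csv"),
                        show_col_types = FALSE)
  iv$care_day <- as.Date(iv$care_day)
  st <- readr::read_csv(file.path(dir, "staffing.csv"), show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  staffing <- tibble::tibble(
    person_id = st$person_id, unit_id = st$unit_id, category = st$category,
    start_time = ts(st$start_time), end_time = ts(st$end_time),
    activity = st$activity, agency = as.logical(st$agency)
  )
  gta <- readr::read_csv(file.path(dir, "ground_truth_acuity.csv"),
                         show_col_types = FALSE)
  gta$care_day <- as.Date(gta$care_day)
  gta$category <- acuity_factor(gta$category)
  gtr <- readr::read_csv(file.path(dir, "ground_truth_ratio.csv"),
                         show_col_types = FALSE)
  gtr$date <- as.Date(gtr$date)
  gtr$shift_type <- shift_factor(gtr$shift_type)
  list(admissions = admissions, interventions = tibble::as_tibble(iv),
       staffing = staffing, ground_truth_acuity = tibble::as_tibble(gta),
       ground_truth_ratio = tibble::as_tibble(gtr),
       cohort_params = params_from_list(manifest$cohort_params, "cohort"),
       roster_params = params_from_list(manifest$roster_params, "roster"),
       manifest = manifest)
}

# --- parameter (de)serialisation -------------------------------------------

params_to_list <- function(p) {
  if (inherits(p, "cohort_params")) {
    list(kind = "cohort",
         n_units = p$n_units, n_weeks = p$n_weeks,
         start_date = format(p$start_date),
         admissions_per_week = as.list(p$admissions_per_week),
         ga_stratum_probs = as.list(p$ga_stratum_probs),
         los_mean_by_stratum = as.list(p$los_mean_by_stratum),
         los_sd_by_stratum = as.list(p$los_sd_by_stratum),
         unit_profiles = lapply(p$unit_profiles, as.list),
         acuity_persistence = p$acuity_persistence,
         initial_acuity = apply(p$initial_acuity_probs_by_stratum, 1, as.list,
                                simplify = FALSE),
         home_leave_prob = p$home_leave_prob,
         noise_flag_prob = p$noise_flag_prob,
         seed = p$seed)
  } else if (inherits(p, "roster_params")) {
    list(kind = "roster",
         target_ratio = p$target_ratio, ratio_sd = p$ratio_sd,
         skill_mix_rn_fraction = p$skill_mix_rn_fraction,
         skill_mix_sd = p$skill_mix_sd,
         specialist_share = as.list(p$specialist_share),
         specialist_share_sd = p$specialist_share_sd,
         shift_length_range = as.list(p$shift_length_range),
         nonclinical_fraction = p$nonclinical_fraction,
         coordinator_probs = as.list(p$coordinator_probs),
         agency_fraction = p$agency_fraction,
         weekend_day_ratio_delta = p$weekend_day_ratio_delta,
         seed = p$seed)
  } else {
    stop("unknown parameter object")
  }
}

params_from_list <- function(x, kind) {
  if (kind == "cohort") {
    init <- do.call(rbind, lapply(x$initial_acuity, unlist))
    rownames(init) <- GA_STRATA
    colnames(init) <- ACUITY_LEVELS
    cohort_params(
      n_units = x$n_units, n_weeks = x$n_weeks, start_date = x$start_date,
      admissions_per_week = unlist(x$admissions_per_week),
      ga_stratum_probs = unlist(x$ga_stratum_probs),
      los_mean_by_stratum = unlist(x$los_mean_by_stratum),
      los_sd_by_stratum = unlist(x$los_sd_by_stratum),
      unit_profiles = lapply(x$unit_profiles, unlist),
      acuity_persistence = x$acuity_persistence,
      initial_acuity_probs_by_stratum = init,
      home_leave_prob = x$home_leave_prob,
      noise_flag_prob = x$noise_flag_prob,
      seed = x$seed
    )
  } else {
    roster_params(
      target_ratio = x$target_ratio, ratio_sd = x$ratio_sd,
      skill_mix_rn_fraction = x$skill_mix_rn_fraction,
      skill_mix_sd = x$skill_mix_sd,
      specialist_share = unlist(x$specialist_share),
      specialist_share_sd = x$specialist_share_sd,
      shift_length_range = unlist(x$shift_length_range),
      nonclinical_fraction = x$nonclinical_fraction,
      coordinator_day_prob = x$coordinator_probs$day,
      coordinator_evening_prob = x$coordinator_probs$evening,
      coordinator_night_prob = x$coordinator_probs$night,
      agency_fraction = x$agency_fraction,
      weekend_day_ratio_delta = x$weekend_day_ratio_delta,
      seed = x$seed
    )
  }
}
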