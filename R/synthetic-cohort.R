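# Synthetic neonatal cohort generator
#
# Emulates the statistical structure the analysis assumes: three NICU-like
# units with Level-4/3/2 acuity profiles, admissions arriving at a constant
# weekly rate with uniform time-of-day, gestational-age strata with
# right-skewed (log-normal) length of stay matched to per-stratum mean/SD,
# and a day-to-day acuity path following a sticky first-order Markov chain
# on {IC, HDC, SC}. Daily intervention flags are emitted deterministically
# from the sampled acuity path via the inverse of the adapted rule table, so
# classification round-trips exactly and the generator ships its own ground
# truth.

GA_STRATA <- c("23-28", "28-32", "32-37", ">37")

# Sticky Markov chain with a prescribed stationary law pi:
# P = a * I + (1 - a) * 1 pi', whose stationary distribution is exactly pi.
sticky_transition <- function(pi, persistence = 0.6) {
  pi <- pi / sum(pi)
  persistence * diag(3) + (1 - persistence) * matrix(pi, 3, 3, byrow = TRUE,
                                                     dimnames = list(ACUITY_LEVELS,
                                                                     ACUITY_LEVELS))
}

# Level-4 / Level-3 / Level-2 style acuity profiles (share of in-hospital
# days in IC / HDC / SC).
default_unit_profiles <- function() {
  list(
    unit_L4 = c(IC = 0.420, HDC = 0.477, SC = 0.103),
    unit_L3 = c(IC = 0.171, HDC = 0.411, SC = 0.418),
    unit_L2 = c(IC = 0.033, HDC = 0.377, SC = 0.590)
  )
}

# Initial acuity at admission by gestational-age stratum (sicker when more
# preterm); converges toward the unit profile over the stay.
default_initial_acuity <- function() {
  m <- rbind(
    `23-28` = c(0.80, 0.15, 0.05),
    `28-32` = c(0.50, 0.35, 0.15),
    `32-37` = c(0.15, 0.45, 0.40),
    `>37`   = c(0.08, 0.35, 0.57)
  )
  colnames(m) <- ACUITY_LEVELS
  m
}

#' Cohort generator parameters
#'
#' Defaults describe a 16-week, three-unit study: admission rates totalling
#' about 35 per week, gestational-age strata 23-28 / 28-32 / 32-37 / >37
#' weeks with probabilities 7.9 / 10.0 / 29.1 / 53.0 %, log-normal length of
#' stay with per-stratum mean (SD) of 37.3 (29.5), 19.6 (15.3), 8.2 (6.7) and
#' 3.6 (3.5) days truncated at 1 day (LOS counted as discharge date -
#' admission date + 1), and per-unit sticky acuity chains whose stationary
#' distributions emulate Level-4/3/2 case mixes.
#'
#' @param n_units Number of units (their ids come from `unit_profiles`).
#' @param n_weeks Simulation length in weeks (>= 1).
#' @param start_date First simulated date (a Monday by default).
#' @param admissions_per_week Expected admissions per unit-week; scalar or one
#'   value per unit.
#' @param ga_stratum_probs Probability over the four GA strata (sums to 1).
#' @param los_mean_by_stratum,los_sd_by_stratum Length-of-stay moments (days).
#' @param unit_profiles Named list of per-unit stationary acuity
#'   distributions; names become unit ids.
#' @param acuity_persistence Day-to-day self-transition weight of the sticky
#'   chain, in \[0, 1).
#' @param acuity_transition Optional explicit row-stochastic 3x3 matrix (or
#'   per-unit list of them) overriding the sticky-chain construction.
#' @param initial_acuity_probs_by_stratum 4x3 matrix of admission-day acuity
#'   probabilities per GA stratum.
#' @param home_leave_prob Probability that a stay of >= 6 days contains one
#'   full home-leave care-day.
#' @param noise_flag_prob Probability of adding a non-qualifying intervention
#'   flag (phototherapy, tube feeding) to any day.
#' @param seed Integer RNG seed.
#' @return Validated object of class `cohort_params`.
#' @export
cohort_params <- function(n_units = 3,
                          n_weeks = 16,
                          start_date = "2024-01-01",
                          admissions_per_week = c(7, 12, 16),
                          ga_stratum_probs = c(0.079, 0.100, 0.291, 0.530),
                          los_mean_by_stratum = c(37.3, 19.6, 8.2, 3.6),
                          los_sd_by_stratum = c(29.5, 15.3, 6.7, 3.5),
                          unit_profiles = default_unit_profiles(),
                          acuity_persistence = 0.6,
                          acuity_transition = NULL,
                          initial_acuity_probs_by_stratum = default_initial_acuity(),
                          home_leave_prob = 0.05,
                          noise_flag_prob = 0.3,
                          seed = 1L) {
  if (n_weeks < 1) stop("n_weeks must be >= 1")
  if (n_units < 1) stop("n_units must be >= 1")
  unit_profiles <- unit_profiles[seq_len(min(n_units, length(unit_profiles)))]
  if (length(unit_profiles) < n_units) {
    extra <- n_units - length(unit_profiles)
    for (i in seq_len(extra)) {
      unit_profiles[[paste0("unit_X", i)]] <- c(IC = 0.15, HDC = 0.4, SC = 0.45)
    }
  }
  admissions_per_week <- rep_len(admissions_per_week, n_units)
  if (any(admissions_per_week < 0)) stop("admissions_per_week must be non-negative")

  ga_stratum_probs <- as.numeric(ga_stratum_probs)
  if (length(ga_stratum_probs) != 4 || abs(sum(ga_stratum_probs) - 1) > 1e-9) {
    stop("ga_stratum_probs must be 4 probabilities summing to 1")
  }
  if (any(los_mean_by_stratum <= 0) || any(los_sd_by_stratum <= 0)) {
    stop("length-of-stay means and SDs must be strictly positive")
  }

  transitions <- build_transitions(acuity_transition, unit_profiles,
                                   acuity_persistence)
  init <- as.matrix(initial_acuity_probs_by_stratum)
  if (!all(dim(init) == c(4, 3)) || any(abs(rowSums(init) - 1) > 1e-9)) {
    stop("initial_acuity_probs_by_stratum must be a 4x3 row-stochastic matrix")
  }
  if (home_leave_prob < 0 || home_leave_prob > 1 ||
      noise_flag_prob < 0 || noise_flag_prob > 1) {
    stop("probabilities must lie in [0, 1]")
  }

  structure(
    list(n_units = as.integer(n_units), n_weeks = as.integer(n_weeks),
         start_date = as.Date(start_date),
         admissions_per_week = admissions_per_week,
         ga_stratum_probs = ga_stratum_probs,
         los_mean_by_stratum = as.numeric(los_mean_by_stratum),
         los_sd_by_stratum = as.numeric(los_sd_by_stratum),
         unit_profiles = unit_profiles,
         acuity_persistence = acuity_persistence,
         acuity_transition = transitions,
         initial_acuity_probs_by_stratum = init,
         home_leave_prob = home_leave_prob,
         noise_flag_prob = noise_flag_prob,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

# Resolve the per-unit transition matrices, validating row-stochasticity.
build_transitions <- function(acuity_transition, unit_profiles, persistence) {
  units <- names(unit_profiles)
  if (is.null(acuity_transition)) {
    out <- lapply(unit_profiles, sticky_transition, persistence = persistence)
  } else if (is.matrix(acuity_transition)) {
    out <- setNames(rep(list(acuity_transition), length(units)), units)
  } else {
    out <- setNames(rep_len(acuity_transition, length(units)), units)
  }
  for (u in units) {
    m <- out[[u]]
    if (!all(dim(m) == c(3, 3)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-9)) {
      stop("acuity transition matrix for ", u, " is not row-stochastic")
    }
  }
  out
}

#' Generate a synthetic cohort
#'
#' Samples admissions and acuity paths, then emits the daily intervention
#' table deterministically from the acuity path via the inverse of the
#' adapted rule set: IC days get invasive respiratory support (sometimes with
#' mechanical support, umbilical lines or parenteral nutrition on top), HDC
#' days get parenteral nutrition and/or non-invasive support without any
#' invasive support, SC days get no qualifying flag. Non-qualifying noise
#' flags (phototherapy, tube feeding) are sprinkled on all categories.
#' Identical parameters (including seed) give identical output.
#'
#' @param params A `cohort_params` object.
#' @return List with `admissions` (incl. optional home-leave columns),
#'   `interventions` (wide logical flags), `ground_truth_acuity`
#'   (patient, care-day, category) and `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  withr::with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(params) {
  units <- names(params$unit_profiles)
  window_start <- care_day_start(params$start_date)
  window_secs <- params$n_weeks * 7 * 86400

  adm_list <- list()
  for (ui in seq_along(units)) {
    n_adm <- stats::rpois(1, params$admissions_per_week[ui] * params$n_weeks)
    if (n_adm == 0) next
    admit <- window_start + floor(stats::runif(n_adm, 0, window_secs) / 60) * 60
    stratum <- sample.int(4, n_adm, replace = TRUE, prob = params$ga_stratum_probs)
    m <- params$los_mean_by_stratum[stratum]
    s <- params$los_sd_by_stratum[stratum]
    sdlog <- sqrt(log(1 + (s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    los <- pmin(180, pmax(1, round(stats::rlnorm(n_adm, meanlog, sdlog))))
    admit_date <- as.Date(admit, tz = "UTC")
    discharge_date <- admit_date + los - 1
    discharge <- as.POSIXct(paste(format(discharge_date), "00:00:00"), tz = "UTC") +
      floor(stats::runif(n_adm, 8 * 60, 20 * 60)) * 60
    short <- discharge <= admit
    discharge[short] <- admit[short] + 2 * 3600
    adm_list[[ui]] <- tibble::tibble(
      unit_id = units[ui],
      patient_id = sprintf("pt_%s_%04d", units[ui], seq_len(n_adm)),
      admit_time = admit, discharge_time = discharge,
      ga_stratum = GA_STRATA[stratum], los_days = los
    )
  }
  admissions <- dplyr::bind_rows(adm_list)
  if (nrow(admissions) == 0 || is.null(adm_list) || length(adm_list) == 0) {
    return(empty_cohort(params))
  }
  admissions$admission_id <- sprintf("adm_%04d", seq_len(nrow(admissions)))

  # acuity paths, one per admission over its admitted care-days
  acuity_list <- vector("list", nrow(admissions))
  for (i in seq_len(nrow(admissions))) {
    first <- care_day(admissions$admit_time[i])
    last <- care_day(admissions$discharge_time[i] - 1)
    days <- seq(first, last, by = "day")
    trans <- params$acuity_transition[[admissions$unit_id[i]]]
    init <- params$initial_acuity_probs_by_stratum[
      match(admissions$ga_stratum[i], GA_STRATA), ]
    path <- integer(length(days))
    path[1] <- sample.int(3, 1, prob = init)
    for (d in seq_along(days)[-1]) {
      path[d] <- sample.int(3, 1, prob = trans[path[d - 1], ])
    }
    acuity_list[[i]] <- tibble::tibble(
      patient_id = admissions$patient_id[i],
      care_day = days,
      category = ACUITY_LEVELS[path]
    )
  }
  acuity <- dplyr::bind_rows(acuity_list)
  acuity$category <- acuity_factor(acuity$category)

  interventions <- flags_from_acuity(acuity, params$noise_flag_prob)

  # home leave: one full middle care-day for a few longer stays
  eligible <- which(admissions$los_days >= 6)
  on_leave <- eligible[stats::runif(length(eligible)) < params$home_leave_prob]
  admissions$home_leave_start <- as.POSIXct(NA_character_, tz = "UTC")
  admissions$home_leave_end <- as.POSIXct(NA_character_, tz = "UTC")
  if (length(on_leave)) {
    mid <- care_day(admissions$admit_time[on_leave]) +
      pmax(1, floor(admissions$los_days[on_leave] / 2))
    admissions$home_leave_start[on_leave] <- care_day_start(mid)
    admissions$home_leave_end[on_leave] <- care_day_start(mid + 1)
  }

  list(admissions = admissions[c("admission_id", "unit_id", "patient_id",
                                 "admit_time", "discharge_time", "ga_stratum",
                                 "los_days", "home_leave_start", "home_leave_end")],
       interventions = interventions,
       ground_truth_acuity = acuity,
       params = params)
}

# Minimal flag set implying the target category under the adapted rules, plus
# harmless noise. Inverse of the default rule table by construction.
flags_from_acuity <- function(acuity, noise_prob) {
  n <- nrow(acuity)
  cat <- as.character(acuity$category)
  ic <- cat == "IC"
  hdc <- cat == "HDC"
  # HDC qualifying combo: 1 = PN only, 2 = NIV only, 3 = both
  combo <- sample.int(3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  tibble::tibble(
    patient_id = acuity$patient_id,
    care_day = acuity$care_day,
    invasive_respiratory_support = ic,
    mechanical_respiratory_support = ic & stats::runif(n) < 0.3,
    noninvasive_respiratory_support = hdc & combo >= 2,
    parenteral_nutrition = (hdc & combo != 2) | (ic & stats::runif(n) < 0.5),
    umbilical_line = ic & stats::runif(n) < 0.4,
    chest_drain = ic & stats::runif(n) < 0.1,
    phototherapy = stats::runif(n) < noise_prob,
    tube_feeding = stats::runif(n) < noise_prob
  )
}

empty_cohort <- function(params) {
  list(
    admissions = tibble::tibble(
      admission_id = character(), unit_id = character(), patient_id = character(),
      admit_time = as.POSIXct(character(), tz = "UTC"),
      discharge_time = as.POSIXct(character(), tz = "UTC"),
      ga_stratum = character(), los_days = integer(),
      home_leave_start = as.POSIXct(character(), tz = "UTC"),
      home_leave_end = as.POSIXct(character(), tz = "UTC")
    ),
    interventions = tibble::tibble(
      patient_id = character(), care_day = as.Date(character()),
      invasive_respiratory_support = logical(),
      mechanical_respiratory_support = logical(),
      noninvasive_respiratory_support = logical(),
      parenteral_nutrition = logical(), umbilical_line = logical(),
      chest_drain = logical(), phototherapy = logical(), tube_feeding = logical()
    ),
    ground_truth_acuity = tibble::tibble(
      patient_id = character(), care_day = as.Date(character()),
      category = acuity_factor(character())
    ),
    params = params
  )
}
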