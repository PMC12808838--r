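# Synthetic cohort/roster generators: determinism, ground truth consistency,
# stratum recovery, roster calibration and fixture round-trips.

test_that("generation is deterministic given (params, seed)", {
  p <- cohort_params(n_weeks = 2, seed = 7, admissions_per_week = c(3, 4, 5))
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$interventions, b$interventions)
  expect_identical(a$ground_truth_acuity, b$ground_truth_acuity)
})

test_that("zero admission rate yields empty, schema-complete tables", {
  out <- generate_cohort(cohort_params(n_weeks = 2, admissions_per_week = 0,
                                       seed = 1))
  expect_equal(nrow(out$admissions), 0)
  expect_equal(nrow(out$interventions), 0)
  expect_equal(nrow(out$ground_truth_acuity), 0)
  expect_true(all(c("admission_id", "unit_id", "patient_id", "admit_time",
                    "discharge_time") %in% names(out$admissions)))
})

test_that("parameter validation rejects broken inputs", {
  expect_error(cohort_params(n_weeks = 0), "n_weeks")
  expect_error(cohort_params(ga_stratum_probs = c(0.5, 0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(cohort_params(los_mean_by_stratum = c(-1, 2, 3, 4)),
               "strictly positive")
  expect_error(cohort_params(acuity_transition = matrix(1, 3, 3)),
               "row-stochastic")
  expect_error(cohort_params(admissions_per_week = -1), "non-negative")
  expect_error(roster_params(target_ratio = 0), "target_ratio")
  expect_error(roster_params(agency_fraction = 1.2), "\\[0, 1\\]")
  expect_error(roster_params(shift_length_range = c(2, 16)), "within \\[4, 15\\]")
})

test_that("GA stratum counts recover the sampling probabilities within 3 SE", {
  probs <- c(0.064, 0.082, 0.286, 0.568)
  out <- generate_cohort(cohort_params(n_units = 1, n_weeks = 16,
                                       admissions_per_week = 125,
                                       ga_stratum_probs = probs, seed = 13))
  n <- nrow(out$admissions)
  expect_gte(n, 1500)
  counts <- table(factor(out$admissions$ga_stratum,
                         levels = c("23-28", "28-32", "32-37", ">37")))
  for (k in 1:4) {
    se <- sqrt(n * probs[k] * (1 - probs[k]))
    expect_lt(abs(counts[k] - n * probs[k]), 3 * se)
  }
})

test_that("intervention flags round-trip to the ground-truth acuity exactly", {
  out <- generate_cohort(cohort_params(n_weeks = 3, seed = 23))
  got <- classify_cohort(out$interventions, default_ruleset(adapted = TRUE),
                         out$admissions)
  key <- merge(got, out$ground_truth_acuity, by = c("patient_id", "care_day"))
  expect_equal(nrow(key), nrow(out$ground_truth_acuity))
  expect_equal(as.character(key$category.x), as.character(key$category.y))
})

test_that("intervention days exist exactly for admitted care-days", {
  out <- generate_cohort(cohort_params(n_weeks = 2, seed = 29,
                                       admissions_per_week = c(4, 4, 4)))
  admitted <- acuitybench:::admitted_care_days(out$admissions)
  expect_equal(nrow(out$interventions), nrow(admitted))
  expect_equal(
    nrow(dplyr::anti_join(out$interventions[c("patient_id", "care_day")],
                          admitted, by = c("patient_id", "care_day"))), 0)
})

test_that("roster calibration hits the target ratio to within the scheduling quantum", {
  for (target in c(0.5, 1.0, 1.5)) {
    b <- simulate_study(cohort_params(n_weeks = 2, seed = 37),
                        roster_params(target_ratio = target, ratio_sd = 0,
                                      nonclinical_fraction = 0, seed = 38))
    led <- build_ledgers(b$admissions, b$ground_truth_acuity, b$staffing,
                         b$windows)
    bt <- benchmark_table(led)
    d <- bt[bt$ratio_defined, ]
    expect_gte(nrow(d), 100)
    # ceiling quantisation: ratio in [target, target + 0.25/recommended]
    expect_true(all(d$ratio >= target - 1e-9))
    expect_true(all(d$ratio <= target + 0.25 / d$recommended_rn_hours + 1e-9))
    expect_lt(abs(median(d$ratio) - target), 0.02)
  }
})

test_that("an all-RN skill mix produces no nursing-assistant hours", {
  b <- simulate_study(cohort_params(n_weeks = 1, seed = 43),
                      roster_params(skill_mix_rn_fraction = 1, skill_mix_sd = 0,
                                    seed = 44))
  expect_false(any(b$staffing$category == "nursing_assistant"))
})

test_that("specialist share and skill mix are recovered from generated rosters", {
  b <- simulate_study(cohort_params(n_weeks = 5, seed = 47),
                      roster_params(specialist_share = 0.73,
                                    specialist_share_sd = 0,
                                    skill_mix_rn_fraction = 0.465,
                                    skill_mix_sd = 0, seed = 48))
  led <- build_ledgers(b$admissions, b$ground_truth_acuity, b$staffing,
                       b$windows)
  expect_gte(nrow(led), 300)
  rn_total <- led$rn_hours + led$rn_spec_hours
  share <- led$rn_spec_hours[rn_total > 0] / rn_total[rn_total > 0]
  expect_lt(abs(median(share) - 0.73), 0.02)
  mix <- rn_total / (rn_total + led$na_hours)
  expect_lt(abs(median(mix, na.rm = TRUE) - 0.465), 0.02)
})

test_that("coordinator presence follows the per-shift-type probabilities", {
  b <- simulate_study(cohort_params(n_weeks = 5, seed = 53),
                      roster_params(seed = 54))
  led <- build_ledgers(b$admissions, b$ground_truth_acuity, b$staffing,
                       b$windows)
  pres <- tapply(led$coordinator_present, led$shift_type, mean)
  expect_gt(pres[["day"]], 0.75)
  expect_lt(pres[["evening"]], 0.1)
  expect_equal(pres[["night"]], 0)
})

test_that("generate_roster refuses a demand table missing a simulated unit-shift", {
  w <- build_windows("2024-01-01", "2024-01-02", "u1")
  demand <- tibble::tibble(unit_id = "u1",
                           date = as.Date("2024-01-01"),
                           shift_type = factor(c("day", "evening", "night")),
                           recommended_rn_hours = 10)
  expect_error(generate_roster(roster_params(), demand, windows = w),
               "u1 2024-01-02")
})

test_that("fixtures round-trip through write/read and regenerate from the manifest", {
  b <- simulate_study(cohort_params(n_weeks = 1, seed = 59,
                                    admissions_per_week = c(3, 3, 3)),
                      roster_params(seed = 60))
  dir <- tempfile("fixture")
  expect_error(write_fixture(b, dir), "does not exist")
  expect_false(any(file.exists(file.path(dir, "admissions.csv"))))
  dir.create(dir)
  write_fixture(b, dir)
  back <- read_fixture(dir)
  expect_equal(back$admissions, b$admissions)
  expect_equal(back$staffing, b$staffing)
  expect_equal(back$interventions, b$interventions)
  expect_equal(as.character(back$ground_truth_acuity$category),
               as.character(b$ground_truth_acuity$category))

  # manifest carries everything needed to regenerate the tables
  regen <- simulate_study(back$cohort_params, back$roster_params)
  expect_identical(regen$admissions, b$admissions)
  expect_identical(regen$staffing, b$staffing)
})
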