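# Window grid construction, interval overlap, infant presence attribution
# and the unit-shift ledgers.

test_that("window grid has 3 x dates x units rows and partitions each care-day", {
  w <- build_windows("2024-01-01", "2024-01-01", "u1")
  expect_equal(nrow(w), 3)
  expect_equal(sum(w$duration), 24)
  expect_equal(w$window_start[w$shift_type == "night"] + 10 * 3600,
               w$window_end[w$shift_type == "night"])
  # night window of date d starts 21:00 on d and is attributed to d
  night <- w[w$shift_type == "night", ]
  expect_equal(format(night$window_start, "%H:%M", tz = "UTC"), "21:00")
  expect_equal(as.Date(night$window_start, tz = "UTC"), night$date)

  # a Saturday's three shifts are all weekend, including the night that ends Sunday
  sat <- build_windows("2024-01-06", "2024-01-06", "u1") # a Saturday
  expect_true(all(sat$weekend))
  mon <- build_windows("2024-01-08", "2024-01-08", "u1")
  expect_false(any(mon$weekend))

  expect_error(build_windows("2024-01-02", "2024-01-01", "u1"), "empty date range")
})

test_that("overlap_hours matches containment, truncation and half-open boundaries", {
  w <- build_windows("2024-01-01", "2024-01-01", "u1")
  day <- w[w$shift_type == "day", ]
  expect_equal(overlap_hours(ts("2024-01-01 08:00:00"), ts("2024-01-01 12:00:00"),
                             day$window_start, day$window_end), 4)
  # raw roster shift truncated to the 7 h analysis window
  expect_equal(overlap_hours(ts("2024-01-01 06:30:00"), ts("2024-01-01 15:30:00"),
                             day$window_start, day$window_end), 7)
  # empty interval
  expect_equal(overlap_hours(ts("2024-01-01 14:00:00"), ts("2024-01-01 14:00:00"),
                             day$window_start, day$window_end), 0)
  expect_error(overlap_hours(ts("2024-01-01 12:00:00"), ts("2024-01-01 08:00:00"),
                             day$window_start, day$window_end), "precedes")
})

test_that("overlap_hours equals minute-by-minute enumeration on random intervals", {
  w <- build_windows("2024-01-01", "2024-01-02", "u1")
  set.seed(101)
  origin <- ts("2024-01-01 00:00:00")
  for (i in 1:150) {
    a <- origin + sample(0:(60 * 48), 1) * 60
    b <- a + sample(1:(60 * 20), 1) * 60
    j <- sample(nrow(w), 1)
    expect_equal(overlap_hours(a, b, w$window_start[j], w$window_end[j]),
                 minute_overlap_oracle(a, b, w$window_start[j], w$window_end[j]),
                 tolerance = 1e-12)
  }
})

test_that("early-morning admissions are charged to the previous date's night shift", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-02 03:00:00",
                              discharge = "2024-01-02 12:00:00"))
  acuity <- make_acuity(adm, "IC")
  w <- build_windows("2024-01-01", "2024-01-02", "u1")
  contrib <- attribute_presence(adm, acuity, w)
  night_prev <- contrib[contrib$shift_type == "night" &
                          contrib$date == as.Date("2024-01-01"), ]
  expect_equal(night_prev$hours, 4) # 03:00-07:00
  expect_equal(sum(contrib$hours), 9) # 03:00-12:00
})

test_that("a full care-day of presence splits 7/7/10 with the day's category", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 07:00:00",
                              discharge = "2024-01-02 07:00:00"))
  acuity <- make_acuity(adm, "HDC")
  w <- build_windows("2024-01-01", "2024-01-02", "u1")
  contrib <- attribute_presence(adm, acuity, w)
  expect_equal(nrow(contrib), 3)
  expect_setequal(contrib$hours, c(7, 7, 10))
  expect_true(all(contrib$category == "HDC"))
  expect_true(all(contrib$date == as.Date("2024-01-01")))
})

test_that("discharge at exactly 14:00 contributes nothing to the evening window", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 10:00:00",
                              discharge = "2024-01-01 14:00:00"))
  contrib <- attribute_presence(adm, make_acuity(adm, "SC"),
                                build_windows("2024-01-01", "2024-01-01", "u1"))
  expect_equal(as.character(unique(contrib$shift_type)), "day")
  expect_equal(sum(contrib$hours), 4)
})

test_that("home leave is subtracted from presence and conservation holds", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 10:00:00",
                              discharge = "2024-01-05 10:00:00"))
  leaves <- tibble::tibble(admission_id = "p1",
                           leave_start = ts("2024-01-02 07:00:00"),
                           leave_end = ts("2024-01-03 07:00:00"))
  acuity <- make_acuity(adm, "HDC")
  w <- build_windows("2023-12-31", "2024-01-05", "u1")
  contrib <- attribute_presence(adm, acuity, w, home_leaves = leaves)
  expect_equal(sum(contrib$hours), 4 * 24 - 24)
  # nothing charged during the leave day
  leave_day <- contrib[contrib$date == as.Date("2024-01-02"), ]
  expect_equal(nrow(leave_day), 0)
})

test_that("presence without a covering acuity day is an error naming the patient", {
  adm <- make_admissions(list(patient_id = "p9", unit = "u1",
                              admit = "2024-01-01 10:00:00",
                              discharge = "2024-01-02 10:00:00"))
  acuity <- tibble::tibble(patient_id = "p9", care_day = as.Date("2024-01-01"),
                           category = "SC")
  w <- build_windows("2024-01-01", "2024-01-02", "u1")
  expect_error(attribute_presence(adm, acuity, w), "p9")
})

test_that("staff hours are window-truncated, nonclinical excluded, coordinators separate", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 07:00:00",
                              discharge = "2024-01-02 07:00:00"))
  acuity <- make_acuity(adm, "IC")
  w <- build_windows("2024-01-01", "2024-01-01", "u1")
  staffing <- tibble::tibble(
    person_id = c("s1", "s2", "s3"),
    unit_id = "u1",
    category = c("RN", "RN_specialist", "coordinator"),
    start_time = ts(c("2024-01-01 07:00:00", "2024-01-01 08:00:00",
                      "2024-01-01 07:00:00")),
    end_time = ts(c("2024-01-01 21:00:00", "2024-01-01 12:00:00",
                    "2024-01-01 14:00:00")),
    activity = c("clinical", "nonclinical", "clinical"),
    agency = FALSE
  )
  led <- build_ledgers(adm, acuity, staffing, w)
  day <- led[led$shift_type == "day", ]
  eve <- led[led$shift_type == "evening", ]
  expect_equal(day$rn_hours, 7)   # 07:00-21:00 truncated to the day window
  expect_equal(eve$rn_hours, 7)   # and its evening share
  expect_equal(sum(led$rn_spec_hours), 0)  # nonclinical excluded entirely
  expect_equal(day$coordinator_hours, 7)
  expect_true(day$coordinator_present)
  expect_false(eve$coordinator_present)
  # coordinator hours are not bedside staff hours
  expect_equal(day$rn_hours + day$rn_spec_hours + day$na_hours, 7)
})

test_that("ledgers are emitted with zero staff hours when there are no staff records", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 07:00:00",
                              discharge = "2024-01-02 07:00:00"))
  led <- build_ledgers(adm, make_acuity(adm, "SC"),
                       tibble::tibble(person_id = character(),
                                      unit_id = character(),
                                      category = character(),
                                      start_time = ts(character()),
                                      end_time = ts(character()),
                                      activity = character(),
                                      agency = logical()),
                       build_windows("2024-01-01", "2024-01-01", "u1"))
  expect_equal(nrow(led), 3)
  expect_true(all(led$rn_hours == 0 & led$na_hours == 0))
  expect_equal(sum(led$sc_hours), 24)
})

test_that("overlapping duplicate staff records are merged with a warning", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 07:00:00",
                              discharge = "2024-01-02 07:00:00"))
  staffing <- tibble::tibble(
    person_id = "s1", unit_id = "u1", category = "RN",
    start_time = ts(c("2024-01-01 07:00:00", "2024-01-01 10:00:00")),
    end_time = ts(c("2024-01-01 12:00:00", "2024-01-01 14:00:00")),
    activity = "clinical", agency = FALSE
  )
  expect_warning(
    led <- build_ledgers(adm, make_acuity(adm, "SC"), staffing,
                         build_windows("2024-01-01", "2024-01-01", "u1")),
    "merged"
  )
  expect_equal(led$rn_hours[led$shift_type == "day"], 7) # union, not 9
})

test_that("staff records for unknown units or with bad categories are rejected", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 07:00:00",
                              discharge = "2024-01-02 07:00:00"))
  w <- build_windows("2024-01-01", "2024-01-01", "u1")
  base <- tibble::tibble(person_id = "s1", unit_id = "u2", category = "RN",
                         start_time = ts("2024-01-01 08:00:00"),
                         end_time = ts("2024-01-01 12:00:00"),
                         activity = "clinical", agency = FALSE)
  expect_error(build_ledgers(adm, make_acuity(adm, "SC"), base, w), "unknown unit")
  bad_cat <- dplyr::mutate(base, unit_id = "u1", category = "surgeon")
  expect_error(build_ledgers(adm, make_acuity(adm, "SC"), bad_cat, w),
               "unknown staff categor")
})

test_that("infant-hour conservation holds on a generated cohort", {
  b <- generate_cohort(cohort_params(n_weeks = 2, seed = 17,
                                     admissions_per_week = c(4, 5, 6)))
  adm <- b$admissions
  # windows covering the full presence span, including post-window discharges
  w <- build_windows(min(care_day(adm$admit_time)),
                     max(care_day(adm$discharge_time)),
                     unique(adm$unit_id))
  contrib <- attribute_presence(adm, b$ground_truth_acuity, w)
  leave_h <- sum(acuitybench:::interval_hours(adm$home_leave_start,
                                              adm$home_leave_end), na.rm = TRUE)
  presence_h <- sum(acuitybench:::interval_hours(adm$admit_time,
                                                 adm$discharge_time)) - leave_h
  expect_equal(sum(contrib$hours), presence_h, tolerance = 1e-9)
})
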