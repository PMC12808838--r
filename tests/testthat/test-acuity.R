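# Rule-set loading, the adapted parenteral-nutrition toggle, and day/cohort
# classification semantics.

test_that("adapted toggle moves PN-without-respiratory-support between HDC and IC", {
  adapted <- default_ruleset(adapted = TRUE)
  original <- default_ruleset(adapted = FALSE)

  pn_only <- c(parenteral_nutrition = TRUE)
  expect_equal(as.character(classify_day(pn_only, adapted)$category), "HDC")
  expect_equal(as.character(classify_day(pn_only, original)$category), "IC")

  # the adapted scheme has no IC rule firing on PN alone
  expect_equal(classify_day(pn_only, adapted)$matched_rule_id, "pn_no_resp")

  # PN with non-invasive support is HDC under both schemes
  pn_niv <- c(parenteral_nutrition = TRUE, noninvasive_respiratory_support = TRUE)
  expect_equal(as.character(classify_day(pn_niv, adapted)$category), "HDC")
  expect_equal(as.character(classify_day(pn_niv, original)$category), "HDC")
})

test_that("classify_day follows first-match semantics and the SC default", {
  rs <- default_ruleset()
  expect_equal(as.character(
    classify_day(c(invasive_respiratory_support = TRUE), rs)$category), "IC")
  empty <- classify_day(stats::setNames(logical(0), character(0)), rs)
  expect_equal(as.character(empty$category), "SC")
  expect_equal(empty$matched_rule_id, "default")
  expect_error(classify_day(c(made_up_flag = TRUE), rs), "unknown intervention")
})

test_that("rule engine agrees with reference category logic on every flag combination", {
  qualifying <- c("mechanical_respiratory_support", "invasive_respiratory_support",
                  "noninvasive_respiratory_support", "umbilical_line",
                  "chest_drain", "parenteral_nutrition")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  names(combos) <- qualifying
  for (adapted in c(TRUE, FALSE)) {
    rs <- default_ruleset(adapted = adapted)
    got <- acuitybench:::classify_flags(combos, rs)$category
    want <- vapply(seq_len(nrow(combos)),
                   function(i) reference_classify(as.list(combos[i, ]), adapted),
                   character(1))
    expect_equal(as.character(got), want,
                 info = paste("adapted =", adapted))
  }
})

test_that("adding a flag never lowers the category under the adapted rules", {
  rs <- default_ruleset(adapted = TRUE)
  vocab <- rs$vocabulary
  set.seed(42)
  sev <- function(cat) match(cat, c("SC", "HDC", "IC")) # higher = sicker
  for (i in 1:200) {
    flags <- stats::setNames(as.list(runif(length(vocab)) < 0.3), vocab)
    base <- reference_classify(flags, TRUE)
    df <- tibble::as_tibble(flags)
    base_got <- as.character(acuitybench:::classify_flags(df, rs)$category)
    off <- vocab[!unlist(flags)]
    if (!length(off)) next
    add <- sample(off, 1)
    df2 <- df
    df2[[add]] <- TRUE
    more <- as.character(acuitybench:::classify_flags(df2, rs)$category)
    expect_gte(sev(more), sev(base_got))
  }
})

test_that("adapted and original schemes differ on exactly the PN-no-respiratory days", {
  adapted <- default_ruleset(TRUE)
  original <- default_ruleset(FALSE)
  vocab <- adapted$vocabulary
  set.seed(99)
  flags <- tibble::as_tibble(stats::setNames(
    lapply(vocab, function(f) runif(500) < 0.25), vocab))
  a <- as.character(acuitybench:::classify_flags(flags, adapted)$category)
  o <- as.character(acuitybench:::classify_flags(flags, original)$category)
  pn_no_resp <- flags$parenteral_nutrition &
    !(flags$invasive_respiratory_support | flags$mechanical_respiratory_support |
        flags$noninvasive_respiratory_support)
  # every difference sits in the PN-no-resp set, toward IC, and only where the
  # adapted scheme did not already say IC (e.g. a chest drain still wins)
  expect_true(all((a != o) == (pn_no_resp & a != "IC")))
  expect_true(all(o[a != o] == "IC"))
})

test_that("rule-set validation rejects malformed documents", {
  write_rules <- function(txt) {
    f <- tempfile(fileext = ".yaml")
    writeLines(txt, f)
    f
  }
  # non-decreasing weights
  f1 <- write_rules(c(
    "vocabulary: [parenteral_nutrition]",
    "rules:",
    "  - {id: r1, category: HDC, any_of: [parenteral_nutrition]}",
    "default_category: SC",
    "weights: {IC: 0.5, HDC: 0.5, SC: 0.25}"
  ))
  expect_error(load_ruleset(f1), "strictly decreasing")
  # undeclared flag
  f2 <- write_rules(c(
    "vocabulary: [parenteral_nutrition]",
    "rules:",
    "  - {id: r1, category: IC, any_of: [unlisted_flag]}",
    "default_category: SC",
    "weights: {IC: 1.0, HDC: 0.5, SC: 0.25}"
  ))
  expect_error(load_ruleset(f2), "undeclared flag")
  # out-of-range weight
  f3 <- write_rules(c(
    "vocabulary: [parenteral_nutrition]",
    "rules:",
    "  - {id: r1, category: IC, any_of: [parenteral_nutrition]}",
    "default_category: SC",
    "weights: {IC: 1.5, HDC: 0.5, SC: 0.25}"
  ))
  expect_error(load_ruleset(f3), "\\(0, 1\\]")
  expect_error(load_ruleset(tempfile()), "not found")
})

test_that("classify_cohort emits one row per admitted care-day", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 10:00:00",
                              discharge = "2024-01-03 12:00:00"))
  iv <- tibble::tibble(
    patient_id = "p1",
    care_day = as.Date(c("2024-01-01", "2024-01-02", "2024-01-03")),
    invasive_respiratory_support = c(TRUE, FALSE, FALSE),
    parenteral_nutrition = c(FALSE, TRUE, FALSE)
  )
  out <- classify_cohort(iv, default_ruleset(), adm)
  expect_equal(nrow(out), 3)
  expect_equal(as.character(out$category), c("IC", "HDC", "SC"))
  expect_equal(attr(out, "n_missing_days"), 0L)
})

test_that("missing intervention days fall back to SC with a warning; orphans error", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 10:00:00",
                              discharge = "2024-01-03 12:00:00"))
  iv <- tibble::tibble(patient_id = "p1", care_day = as.Date("2024-01-01"),
                       invasive_respiratory_support = TRUE)
  expect_warning(out <- classify_cohort(iv, default_ruleset(), adm),
                 "missing-day policy")
  expect_equal(nrow(out), 3)
  expect_equal(as.character(out$category), c("IC", "SC", "SC"))
  expect_equal(out$matched_rule_id[2:3], c("missing_day", "missing_day"))
  expect_equal(attr(out, "n_missing_days"), 2L)
  expect_error(classify_cohort(iv, default_ruleset(), adm,
                               missing_policy = "error"),
               "without an intervention record")

  orphan <- dplyr::bind_rows(iv, tibble::tibble(
    patient_id = "p1", care_day = as.Date("2024-02-01"),
    invasive_respiratory_support = FALSE))
  expect_error(classify_cohort(orphan, default_ruleset(), adm),
               "outside any admission")
})

test_that("duplicate (patient, care-day) intervention records are rejected", {
  adm <- make_admissions(list(patient_id = "p1", unit = "u1",
                              admit = "2024-01-01 10:00:00",
                              discharge = "2024-01-02 12:00:00"))
  iv <- tibble::tibble(patient_id = c("p1", "p1"),
                       care_day = as.Date(c("2024-01-01", "2024-01-01")),
                       parenteral_nutrition = c(TRUE, FALSE))
  expect_error(classify_cohort(iv, default_ruleset(), adm), "more than one")
})
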