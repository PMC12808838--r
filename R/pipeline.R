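# End-to-end pipeline
#
# classify -> account -> benchmark -> summarise, with all stage outputs
# written as CSV, a run manifest (config, rule-file hash, versions) and a
# short human-readable report. All tabular outputs are deterministic given
# the inputs; rerunning the same configuration reproduces them byte for
# byte.

#' Run the full benchmarking pipeline
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `admissions`, `interventions`, `staffing` — input CSV paths (or
#'   in-memory tables); `rules` — rule YAML path (default: packaged table);
#'   `adapted` (default TRUE); `include_coordinator` (default FALSE);
#'   `from`, `to` — analysis date range (defaults: span covered by both the
#'   admission and staffing data); `out_dir` — output directory (created if
#'   missing); `figures` (default TRUE).
#' @return Invisibly, a list with `acuity`, `windows`, `ledgers`,
#'   `benchmark`, `skill_mix`, `summary`, `tests` and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  cfg$adapted <- cfg$adapted %||% TRUE
  cfg$include_coordinator <- cfg$include_coordinator %||% FALSE
  cfg$figures <- cfg$figures %||% TRUE

  read_input <- function(x, what, reader) {
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    if (is.null(x) || !file.exists(x)) {
      stop(what, " file not found: ", x %||% "<missing>")
    }
    reader(x)
  }
  inputs_from_dir <- !is.null(cfg$fixture_dir)
  if (inputs_from_dir) {
    bundle <- read_fixture(cfg$fixture_dir)
    admissions <- bundle$admissions
    interventions <- bundle$interventions
    staffing <- bundle$staffing
  } else {
    admissions <- read_input(cfg$admissions, "admissions", read_admissions_csv)
    interventions <- read_input(cfg$interventions, "interventions",
                                read_interventions_csv)
    staffing <- read_input(cfg$staffing, "staffing", read_staffing_csv)
  }
  message("stage classify: ", nrow(admissions), " admissions, ",
          nrow(interventions), " intervention days read")

  ruleset <- load_ruleset(cfg$rules, adapted = cfg$adapted)
  acuity <- classify_cohort(interventions, ruleset, admissions)
  n_missing <- attr(acuity, "n_missing_days")
  message("stage classify: ", nrow(acuity), " care-days classified (",
          n_missing, " missing-day fallback(s))")

  adm_time <- parse_timestamp(admissions$admit_time)
  dis_time <- parse_timestamp(admissions$discharge_time)
  staff_start <- parse_timestamp(staffing$start_time)
  from <- as.Date(cfg$from %||% max(min(care_day(adm_time)),
                                    min(care_day(staff_start))))
  to <- as.Date(cfg$to %||% min(max(care_day(dis_time - 1)),
                                max(care_day(staff_start))))
  units <- sort(unique(c(admissions$unit_id, staffing$unit_id)))
  windows <- build_windows(from, to, units)
  message("stage account: ", nrow(windows), " shift windows (", from, " to ",
          to, ", ", length(units), " unit(s))")

  ledgers <- build_ledgers(admissions, acuity, staffing, windows)
  benchmark <- benchmark_table(ledgers, weights = ruleset$weights,
                               include_coordinator = cfg$include_coordinator)
  skill_mix <- skill_mix_summary(ledgers)
  summary <- summarize_benchmark(benchmark)
  tests <- pipeline_tests(benchmark, ledgers)
  message("stage benchmark: ", summary$headline$n_ratio_defined,
          " ratio-defined shifts, ",
          sprintf("%.1f%%", 100 * summary$headline$fraction_understaffed),
          " understaffed")

  out <- list(acuity = acuity, windows = windows, ledgers = ledgers,
              benchmark = benchmark, skill_mix = skill_mix, summary = summary,
              tests = tests, ruleset = ruleset)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out$paths <- write_pipeline_outputs(out, cfg)
  }
  invisible(out)
}

# KW: specialist share across shift types within each unit.
# MW: provision ratio weekday vs weekend, per shift type (pooled over units
# and per unit).
pipeline_tests <- function(benchmark, ledgers) {
  tests <- list()
  rn_total <- ledgers$rn_hours + ledgers$rn_spec_hours
  share <- ifelse(rn_total > 0, ledgers$rn_spec_hours / rn_total, NA_real_)
  for (u in unique(ledgers$unit_id)) {
    groups <- lapply(SHIFT_LEVELS, function(s) {
      share[ledgers$unit_id == u & ledgers$shift_type == s & !is.na(share)]
    })
    if (all(lengths(groups) >= 1) && sum(lengths(groups)) >= 3) {
      tests <- c(tests, list(kruskal_wallis(
        groups, groups = paste0("specialist share by shift type, ", u))))
    }
  }
  mw_sets <- c(list(pooled = benchmark),
               split(benchmark, benchmark$unit_id))
  for (nm in names(mw_sets)) {
    b <- mw_sets[[nm]]
    for (s in SHIFT_LEVELS) {
      wd <- b$ratio[b$shift_type == s & !b$weekend & b$ratio_defined]
      we <- b$ratio[b$shift_type == s & b$weekend & b$ratio_defined]
      if (length(wd) && length(we)) {
        tests <- c(tests, list(mann_whitney(
          wd, we,
          groups = paste0("ratio weekday vs weekend, ", s, " shift, ", nm))))
      }
    }
  }
  tests_to_table(tests)
}

write_pipeline_outputs <- function(out, cfg) {
  dir <- cfg$out_dir
  sig <- function(df) {
    df <- tibble::as_tibble(df)
    for (col in names(df)) {
      if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], 6)
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_timestamp(df[[col]])
    }
    df
  }
  paths <- list(
    acuity = file.path(dir, "acuity.csv"),
    ledgers = file.path(dir, "ledgers.csv"),
    benchmark = file.path(dir, "benchmark.csv"),
    skill_mix = file.path(dir, "skill_mix.csv"),
    summaries = file.path(dir, "summaries.csv"),
    tests = file.path(dir, "tests.csv"),
    headline = file.path(dir, "headline.csv"),
    report = file.path(dir, "report.md"),
    manifest = file.path(dir, "run_manifest.yaml")
  )
  readr::write_csv(out$acuity, paths$acuity, na = "")
  readr::write_csv(sig(out$ledgers), paths$ledgers, na = "")
  readr::write_csv(sig(out$benchmark), paths$benchmark, na = "")
  readr::write_csv(sig(out$skill_mix), paths$skill_mix, na = "")
  readr::write_csv(sig(out$summary$by_group), paths$summaries, na = "")
  readr::write_csv(sig(out$tests), paths$tests, na = "")
  readr::write_csv(sig(out$summary$headline), paths$headline, na = "")

  manifest <- list(
    package_version = as.character(utils::packageVersion("acuitybench")),
    rule_file = out$ruleset$source,
    rule_hash = out$ruleset$source_hash,
    adapted = out$ruleset$adapted,
    include_coordinator = isTRUE(cfg$include_coordinator),
    date_range = c(format(min(out$windows$date)), format(max(out$windows$date))),
    n_shifts = out$summary$headline$n_shifts
  )
  yaml::write_yaml(manifest, paths$manifest)
  writeLines(render_report_text(out), paths$report)

  if (isTRUE(cfg$figures)) {
    paths$figures <- tryCatch(
      render_figures(out$benchmark, out$ledgers, out$acuity, dir),
      error = function(e) {
        warning("figure rendering skipped: ", conditionMessage(e))
        NULL
      }
    )
  }
  paths
}

render_report_text <- function(out) {
  h <- out$summary$headline
  rr <- out$summary$recommended_range
  c(
    "# Acuity-adjusted RN staffing benchmark",
    "",
    sprintf("Shifts analysed: %d (%d with a defined provision ratio)",
            h$n_shifts, h$n_ratio_defined),
    sprintf("Fraction understaffed (ratio < 1.0): %.1f%%",
            100 * h$fraction_understaffed),
    sprintf("Median RN provision ratio: %.2f (IQR %.2f, range %.2f-%.2f)",
            h$median_ratio, h$iqr_ratio, h$min_ratio, h$max_ratio),
    "",
    "Recommended whole-shift RN count per unit (min / mean / max):",
    sprintf("  %s: %.1f / %.1f / %.1f", rr$unit_id,
            rr$min_recommended_rn_count, rr$mean_recommended_rn_count,
            rr$max_recommended_rn_count),
    "",
    sprintf("Rule set: %s scheme, hash %s",
            if (out$ruleset$adapted) "adapted" else "original",
            out$ruleset$source_hash)
  )
}

#' One-command demonstration run
#'
#' Simulates a small (4-week) study, writes the fixture, runs the full
#' pipeline on it and writes all outputs. Two runs with the same seed produce
#' byte-identical tabular outputs.
#'
#' @param out_dir Output directory (created; fixture under `fixture/`,
#'   results under `results/`).
#' @param seed Integer seed for both generators.
#' @param n_weeks Simulated weeks (default 4).
#' @return Invisibly, the pipeline result list.
#' @export
run_demo <- function(out_dir, seed = 7L, n_weeks = 4L) {
  fixture_dir <- file.path(out_dir, "fixture")
  results_dir <- file.path(out_dir, "results")
  dir.create(fixture_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- simulate_study(
    cohort_params(n_weeks = n_weeks, seed = seed),
    roster_params(seed = seed + 1L)
  )
  write_fixture(bundle, fixture_dir)
  res <- run_pipeline(list(
    fixture_dir = fixture_dir,
    out_dir = results_dir,
    from = format(bundle$cohort_params$start_date),
    to = format(bundle$cohort_params$start_date + n_weeks * 7 - 1)
  ))
  invisible(res)
}

# --- CSV readers with explicit schemas -------------------------------------

#' Read an admissions CSV
#' @param path File path.
#' @return Tibble with parsed timestamps.
#' @export
read_admissions_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("unit_id", "patient_id", "admit_time", "discharge_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("admissions CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$admit_time <- parse_timestamp(df$admit_time)
  df$discharge_time <- parse_timestamp(df$discharge_time)
  for (col in c("home_leave_start", "home_leave_end")) {
    if (col %in% names(df)) {
      df[[col]] <- parse_timestamp(ifelse(df[[col]] == "", NA, df[[col]]))
    }
  }
  if ("los_days" %in% names(df)) df$los_days <- as.integer(df$los_days)
  df
}

#' Read a wide interventions CSV
#' @param path File path.
#' @return Tibble with `care_day` as Date and logical flag columns.
#' @export
read_interventions_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("patient_id", "care_day") %in% names(df))) {
    stop("interventions CSV needs patient_id and care_day columns")
  }
  df$care_day <- as.Date(df$care_day)
  for (col in setdiff(names(df), c("patient_id", "care_day"))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Read a staffing CSV
#' @param path File path.
#' @return Tibble with parsed timestamps and logical agency flag.
#' @export
read_staffing_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("person_id", "unit_id", "category", "start_time", "end_time",
            "activity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("staffing CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$start_time <- parse_timestamp(df$start_time)
  df$end_time <- parse_timestamp(df$end_time)
  df$agency <- if ("agency" %in% names(df)) as.logical(df$agency) else FALSE
  df
}
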