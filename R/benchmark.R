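# Acuity-adjusted staffing benchmark
#
# The recommended registered-nurse workload for a unit-shift is the
# acuity-weighted sum of infant-hours,
#
#   recommended_rn_hours = 1.0 * IC_hours + 0.5 * HDC_hours + 0.25 * SC_hours,
#
# the hour-denominated form of the 1:1 / 1:2 / 1:4 infant-to-nurse staffing
# standard. Dividing by the window duration converts hours to a whole-shift
# nurse count. The provision ratio is provided clinical RN hours (registered
# nurses plus specialist registered nurses; nursing assistants excluded;
# coordinators excluded unless configured otherwise) over recommended hours;
# a ratio below 1.0 flags the shift as understaffed.

#' Recommended registered-nurse hours for a unit-shift
#'
#' @param infant_hours Named numeric vector or list with elements `IC`, `HDC`,
#'   `SC` (hours), or a data frame with those columns (vectorised).
#' @param weights Acuity weights, strictly decreasing, default
#'   `c(IC = 1, HDC = 0.5, SC = 0.25)`.
#' @return Numeric hours (one value per row for data-frame input).
#' @export
#' @examples
#' recommended_rn_hours(c(IC = 28, HDC = 42, SC = 56)) # 63
recommended_rn_hours <- function(infant_hours,
                                 weights = c(IC = 1, HDC = 0.5, SC = 0.25)) {
  if (is.data.frame(infant_hours)) {
    h <- infant_hours
  } else {
    h <- tibble::as_tibble(as.list(unlist(infant_hours)))
  }
  missing <- setdiff(ACUITY_LEVELS, names(h))
  if (length(missing)) stop("infant_hours missing: ", paste(missing, collapse = ", "))
  if (any(unlist(h[ACUITY_LEVELS]) < 0, na.rm = TRUE)) {
    stop("infant hours must be non-negative")
  }
  weights <- weights[ACUITY_LEVELS]
  as.numeric(h$IC * weights[["IC"]] + h$HDC * weights[["HDC"]] +
             h$SC * weights[["SC"]])
}

#' Registered-nurse provision ratio
#'
#' Vectorised. A zero recommendation (empty unit-shift) yields an undefined
#' ratio: `ratio = NA`, `ratio_defined = FALSE`, excluded from ratio
#' summaries but retained in shift counts.
#'
#' @param provided Provided clinical RN hours (RN + specialist RN).
#' @param recommended Recommended RN hours from [recommended_rn_hours()].
#' @return Tibble with `ratio`, `understaffed` (`ratio < 1`), `ratio_defined`.
#' @export
#' @examples
#' provision_ratio(38, 50) # ratio 0.76, understaffed
provision_ratio <- function(provided, recommended) {
  if (any(provided < 0) || any(recommended < 0)) {
    stop("hours must be non-negative")
  }
  defined <- recommended > 0
  ratio <- ifelse(defined, provided / recommended, NA_real_)
  tibble::tibble(ratio = ratio,
                 understaffed = ratio < 1.0,
                 ratio_defined = defined)
}

#' Per-shift benchmark table
#'
#' Augments each ledger row with the recommended RN hours and count, provided
#' RN hours, provision ratio, understaffing flag, and the two skill-mix
#' proportions (RN share of nursing-staff hours; specialist share of RN
#' hours).
#'
#' @param ledgers Ledger table from [build_ledgers()].
#' @param weights Acuity weights (see [recommended_rn_hours()]).
#' @param include_coordinator Count coordinator hours as provided RN hours
#'   (default FALSE: coordinators are accounted separately).
#' @return Tibble of benchmark rows, one per unit-shift.
#' @export
benchmark_table <- function(ledgers, weights = c(IC = 1, HDC = 0.5, SC = 0.25),
                            include_coordinator = FALSE) {
  ledgers <- tibble::as_tibble(ledgers)
  rec <- recommended_rn_hours(
    tibble::tibble(IC = ledgers$ic_hours, HDC = ledgers$hdc_hours,
                   SC = ledgers$sc_hours),
    weights
  )
  provided <- ledgers$rn_hours + ledgers$rn_spec_hours +
    if (include_coordinator) ledgers$coordinator_hours else 0
  pr <- provision_ratio(provided, rec)
  total_staff <- provided + ledgers$na_hours
  rn_total <- ledgers$rn_hours + ledgers$rn_spec_hours

  tibble::tibble(
    unit_id = ledgers$unit_id,
    date = ledgers$date,
    shift_type = ledgers$shift_type,
    weekend = ledgers$weekend,
    duration = ledgers$duration,
    recommended_rn_hours = rec,
    recommended_rn_count = rec / ledgers$duration,
    provided_rn_hours = provided,
    ratio = pr$ratio,
    ratio_defined = pr$ratio_defined,
    understaffed = pr$understaffed,
    rn_fraction_of_staff = ifelse(total_staff > 0, rn_total / total_staff, NA_real_),
    specialist_share = ifelse(rn_total > 0, ledgers$rn_spec_hours / rn_total, NA_real_)
  )
}

# --- summaries --------------------------------------------------------------

# Mean (SD, normal-approximation 95% CI), median (IQR as Q3 - Q1, linear
# interpolation quantiles). NA values are dropped by callers beforehand.
summary_block <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) stats::sd(x) else 0
  half <- 1.96 * s / sqrt(n)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = n, mean = m, sd = s,
                 ci95_low = m - half, ci95_high = m + half,
                 median = q[2], iqr = q[3] - q[1])
}

#' Skill-mix summaries per group
#'
#' Computes the two per-shift skill-mix proportions first — RN share of total
#' nursing-staff hours and specialist share of RN hours — then summarises
#' each within groups (median/IQR, mean/SD/95% CI). Shifts with a zero
#' denominator are excluded from the summary and counted in `n_excluded`.
#'
#' @param ledgers Ledger table from [build_ledgers()].
#' @param grouping Character vector of grouping columns (subset of
#'   `unit_id`, `shift_type`, `weekend`), default `c("unit_id", "shift_type")`.
#' @return Tibble: one row per (measure, group) with summary columns.
#' @export
skill_mix_summary <- function(ledgers, grouping = c("unit_id", "shift_type")) {
  ledgers <- tibble::as_tibble(ledgers)
  rn_total <- ledgers$rn_hours + ledgers$rn_spec_hours
  total <- rn_total + ledgers$na_hours
  per_shift <- dplyr::bind_rows(
    dplyr::mutate(ledgers[grouping],
                  measure = "rn_fraction_of_staff",
                  value = ifelse(total > 0, rn_total / total, NA_real_)),
    dplyr::mutate(ledgers[grouping],
                  measure = "specialist_share",
                  value = ifelse(rn_total > 0, ledgers$rn_spec_hours / rn_total,
                                 NA_real_))
  )
  grp <- dplyr::group_by(per_shift,
                         dplyr::across(dplyr::all_of(c("measure", grouping))))
  out <- dplyr::reframe(grp, {
    v <- .data$value
    blk <- summary_block(v[!is.na(v)])
    blk$n_excluded <- sum(is.na(v))
    blk
  })
  empty <- out$n == 0
  if (any(empty)) {
    warning(sum(empty), " group(s) had no defined skill-mix values and were omitted")
    out <- out[!empty, ]
  }
  out
}

#' Benchmark headline metrics and grouped summaries
#'
#' Headline metrics are computed over ratio-defined rows only: the fraction of
#' understaffed shifts, median/IQR/min/max of the provision ratio, and the
#' range of the recommended whole-shift RN count per unit. Grouped summaries
#' follow a unit x shift-type x weekday/weekend layout (or pooled).
#'
#' @param rows Benchmark table from [benchmark_table()].
#' @param grouping Character vector of grouping columns, or `NULL` for pooled.
#' @return List with `headline` (one-row tibble), `recommended_range` (per
#'   unit), and `by_group` (summary blocks of ratio and recommended count).
#' @export
summarize_benchmark <- function(rows,
                                grouping = c("unit_id", "shift_type", "weekend")) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0) stop("no benchmark rows to summarise")
  def <- rows[rows$ratio_defined, ]
  headline <- tibble::tibble(
    n_shifts = nrow(rows),
    n_ratio_defined = nrow(def),
    fraction_understaffed = mean(def$understaffed),
    median_ratio = stats::median(def$ratio),
    iqr_ratio = unname(diff(stats::quantile(def$ratio, c(0.25, 0.75), type = 7))),
    min_ratio = min(def$ratio),
    max_ratio = max(def$ratio)
  )
  recommended_range <- dplyr::summarise(
    dplyr::group_by(rows, .data$unit_id),
    min_recommended_rn_count = min(.data$recommended_rn_count),
    max_recommended_rn_count = max(.data$recommended_rn_count),
    mean_recommended_rn_count = mean(.data$recommended_rn_count),
    .groups = "drop"
  )
  by_group <- if (is.null(grouping)) {
    dplyr::mutate(summary_block(def$ratio), measure = "ratio", .before = 1)
  } else {
    grp <- dplyr::group_by(
      dplyr::bind_rows(
        dplyr::mutate(def[c(grouping)], measure = "ratio", value = def$ratio),
        dplyr::mutate(rows[c(grouping)], measure = "recommended_rn_count",
                      value = rows$recommended_rn_count)
      ),
      dplyr::across(dplyr::all_of(c("measure", grouping)))
    )
    dplyr::reframe(grp, summary_block(.data$value))
  }
  list(headline = headline, recommended_range = recommended_range,
       by_group = by_group)
}
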