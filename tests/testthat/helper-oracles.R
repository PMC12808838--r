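# Independent oracles used by the tests. These deliberately avoid the
# package's interval arithmetic and test machinery: hours are counted by
# brute-force minute enumeration and p-values by exhaustive permutation
# enumeration built on stats:: primitives.

# Hours of [start, end) falling inside [win_start, win_end), counted one
# minute at a time. All inputs must be minute-aligned POSIXct.
minute_overlap_oracle <- function(start, end, win_start, win_end) {
  if (win_end <= win_start) return(0)
  minutes <- seq(from = win_start, to = win_end - 60, by = "1 min")
  sum(minutes >= start & minutes < end) / 60
}

# Per-window minute accounting of a set of intervals (one row per interval).
# Returns total hours per window row.
minute_window_hours_oracle <- function(intervals, windows) {
  vapply(seq_len(nrow(windows)), function(w) {
    tot <- 0
    for (i in seq_len(nrow(intervals))) {
      tot <- tot + minute_overlap_oracle(intervals$start[i], intervals$end[i],
                                         windows$window_start[w],
                                         windows$window_end[w])
    }
    tot
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by enumerating every allocation of the
# pooled sample into the two groups: p = P(|U - mu| >= |U_obs - mu|).
mw_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  picks <- utils::combn(n, n1)
  u_all <- apply(picks, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exhaustive Kruskal-Wallis permutation p, computing each arrangement's
# tie-corrected H with stats::kruskal.test (independent of the package's
# statistic code). p = P(H >= H_obs).
kw_enumeration_oracle <- function(samples) {
  values <- unlist(samples)
  sizes <- lengths(samples)
  g <- factor(rep(seq_along(sizes), sizes))
  h_obs <- unname(stats::kruskal.test(values, g)$statistic)
  n <- length(values)
  count <- 0L
  total <- 0L
  recurse <- function(remaining, sizes_left, assigned) {
    if (length(sizes_left) == 1) {
      perm <- c(assigned, remaining)
      h <- unname(stats::kruskal.test(values[perm], g)$statistic)
      count <<- count + (h >= h_obs - 1e-9)
      total <<- total + 1L
      return(invisible())
    }
    for (p in utils::combn(remaining, sizes_left[1], simplify = FALSE)) {
      recurse(setdiff(remaining, p), sizes_left[-1], c(assigned, p))
    }
  }
  recurse(seq_len(n), sizes, integer())
  count / total
}

# Reference three-level classification logic, written straight from the
# category definitions rather than through the rule engine.
reference_classify <- function(flags, adapted) {
  get <- function(f) isTRUE(flags[[f]])
  resp <- get("invasive_respiratory_support") ||
    get("mechanical_respiratory_support") ||
    get("noninvasive_respiratory_support")
  if (get("invasive_respiratory_support") ||
      get("mechanical_respiratory_support") || get("chest_drain")) {
    return("IC")
  }
  if (get("parenteral_nutrition") && !resp) {
    return(if (adapted) "HDC" else "IC")
  }
  if (get("noninvasive_respiratory_support") || get("umbilical_line")) {
    return("HDC")
  }
  "SC"
}

# Minute-aligned POSIXct helper.
ts <- function(x) as.POSIXct(x, tz = "UTC")

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny admission table builder.
make_admissions <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(admission_id = r$id %||% r$patient_id,
                   unit_id = r$unit, patient_id = r$patient_id,
                   admit_time = ts(r$admit), discharge_time = ts(r$discharge))
  }))
}

# Constant-category acuity covering every admitted care-day.
make_acuity <- function(admissions, category = "HDC") {
  days <- acuitybench:::admitted_care_days(admissions)
  tibble::tibble(patient_id = days$patient_id, care_day = days$care_day,
                 category = category)
}
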