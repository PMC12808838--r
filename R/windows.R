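# Shift analysis windows
#
# The three units roster staff on overlapping raw shifts (roughly 07:00-15:30,
# 13:30-21:30, 21:00-07:15), but the analysis truncates presence to fixed,
# non-overlapping provision windows so that every hour of the 07:00-07:00
# care-day is charged to exactly one shift:
#
#   day      [07:00, 14:00)   7 h
#   evening  [14:00, 21:00)   7 h
#   night    [21:00, 07:00+1) 10 h
#
# The night window is attributed to the date it starts on, so a Saturday
# night shift running into Sunday morning counts as a weekend Saturday shift.

SHIFT_OFFSETS <- c(day = 7, evening = 14, night = 21)   # hours after midnight
SHIFT_DURATIONS <- c(day = 7, evening = 7, night = 10)  # hours

#' Build the shift-window grid
#'
#' Creates one row per unit, date and shift type over an inclusive date range.
#' The three windows of a date partition its 07:00-anchored care-day exactly
#' (durations 7 + 7 + 10 = 24). The weekend flag is set from the attributed
#' date, so the night window starting Saturday 21:00 is a weekend shift even
#' though most of it falls on Sunday.
#'
#' @param start_date,end_date Inclusive date range (anything `as.Date()` accepts).
#' @param units Character vector of unit identifiers.
#' @return A tibble with columns `unit_id`, `date`, `shift_type`, `window_start`,
#'   `window_end`, `duration` (hours) and `weekend`.
#' @export
#' @examples
#' w <- build_windows("2024-01-01", "2024-01-01", "unitA")
#' sum(w$duration) # 24
build_windows <- function(start_date, end_date, units) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (length(units) < 1) stop("at least one unit is required")
  if (is.na(start_date) || is.na(end_date)) stop("invalid date range")
  if (end_date < start_date) stop("empty date range: end_date precedes start_date")

  grid <- tidyr::expand_grid(
    unit_id = as.character(units),
    date = seq(start_date, end_date, by = "day"),
    shift_type = shift_factor(SHIFT_LEVELS)
  )
  midnight <- as.POSIXct(paste(format(grid$date), "00:00:00"), tz = "UTC")
  offset <- unname(SHIFT_OFFSETS[as.character(grid$shift_type)])
  duration <- unname(SHIFT_DURATIONS[as.character(grid$shift_type)])
  dplyr::mutate(grid,
    window_start = midnight + offset * 3600,
    window_end = .data$window_start + duration * 3600,
    duration = duration,
    weekend = is_weekend(.data$date)
  )
}

#' Overlap between a half-open interval and a window, in hours
#'
#' Intervals are half-open `[start, end)` throughout the package: a discharge
#' at exactly 14:00 contributes nothing to the evening window, and the raw
#' roster overlap periods (13:30-14:00, 21:00-21:30, 07:00-07:15) are each
#' charged to exactly one window. Vectorised over all four arguments.
#'
#' @param start,end Interval bounds (POSIXct).
#' @param window_start,window_end Window bounds (POSIXct).
#' @return Numeric hours of intersection (0 when disjoint), exact to the
#'   second.
#' @export
#' @examples
#' w <- build_windows("2024-01-01", "2024-01-01", "u")[1, ]
#' overlap_hours(as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
#'               as.POSIXct("2024-01-01 12:00:00", tz = "UTC"),
#'               w$window_start, w$window_end) # 4
overlap_hours <- function(start, end, window_start, window_end) {
  if (any(end < start)) stop("interval end precedes start")
  lo <- pmax(as.numeric(start), as.numeric(window_start))
  hi <- pmin(as.numeric(end), as.numeric(window_end))
  pmax(0, hi - lo) / 3600
}
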