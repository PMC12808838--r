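# Time conventions
#
# All timestamps are timezone-naive local clock times, represented internally
# as POSIXct in UTC (so arithmetic is free of DST artefacts). The care-day is
# the 24-hour period anchored at 07:00: care-day d spans [d 07:00, d+1 07:00).
# A timestamp between 00:00 and 06:59 therefore belongs to the previous
# calendar date's care-day, which is what attributes early-morning admissions
# to the preceding night shift.

CARE_DAY_ANCHOR <- 7L # hours after midnight

#' Care-day of a timestamp
#'
#' Maps a timestamp to the calendar date of the 07:00-anchored care-day that
#' contains it. Times between 00:00 and 06:59 map to the previous date.
#'
#' @param time POSIXct vector.
#' @return Date vector.
#' @export
#' @examples
#' care_day(as.POSIXct("2024-01-02 03:00:00", tz = "UTC")) # "2024-01-01"
care_day <- function(time) {
  stopifnot(inherits(time, "POSIXct"))
  as.Date(time - CARE_DAY_ANCHOR * 3600, tz = "UTC")
}

#' Start timestamp (07:00) of a care-day
#'
#' @param date Date vector.
#' @return POSIXct vector at 07:00 on `date`.
#' @export
care_day_start <- function(date) {
  date <- as.Date(date)
  as.POSIXct(paste(format(date), "07:00:00"), tz = "UTC")
}

# Parse "YYYY-MM-DD HH:MM:SS" local-naive timestamps.
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(lubridate_free_utc(x))
  }
  out <- as.POSIXct(as.character(x), tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

# Force the UTC representation without shifting the clock reading.
lubridate_free_utc <- function(x) {
  attr(x, "tzone") <- "UTC"
  x
}

format_timestamp <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

# Difference end - start in fractional hours.
interval_hours <- function(start, end) {
  as.numeric(difftime(end, start, units = "hours"))
}

is_weekend <- function(date) format(as.Date(date), "%u") %in% c("6", "7")
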