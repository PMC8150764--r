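#' Construct a validated raw recording
#'
#' One participant-visit's tri-axial wrist signal at its native sampling
#' rate. No resampling is ever performed: mixed cohorts (30/80/100 Hz) keep
#' each recording at its declared rate and all downstream window sizes are
#' expressed in samples at that rate.
#'
#' @param participant_id,visit_id Identifier strings.
#' @param rate_hz Declared sampling rate: 30, 80 or 100 Hz. The median
#'   sample spacing of `t` must agree with `1/rate_hz` within 1%.
#' @param t Time in seconds since recording start; strictly increasing.
#' @param x,y,z Acceleration per axis in g; same length as `t`.
#' @return An object of class `"wpa_recording"`.
#' @export
raw_recording <- function(participant_id, visit_id, rate_hz, t, x, y, z) {
  if (!rate_hz %in% c(30, 80, 100)) {
    stop_input("rate_hz must be one of 30, 80, 100")
  }
  n <- length(t)
  if (n == 0) stop_input("recording is empty")
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop_input("t, x, y, z must have equal length")
  }
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop_input("timestamps must be strictly increasing")
    med <- stats::median(dt)
    if (abs(med - 1 / rate_hz) > 0.01 / rate_hz) {
      stop_input(sprintf(
        "median sample spacing %.6f s inconsistent with declared %g Hz",
        med, rate_hz))
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         visit_id = as.character(visit_id), rate_hz = rate_hz,
         t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z)),
    class = "wpa_recording"
  )
}

#' @export
print.wpa_recording <- function(x, ...) {
  cat(sprintf("<wpa_recording> %s / %s: %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$visit_id, length(x$t), x$rate_hz,
              length(x$t) / x$rate_hz))
  invisible(x)
}

#' Read a raw recording from CSV
#'
#' Canonical dialect: comma-separated with header `timestamp,x,y,z`,
#' timestamp in seconds (numeric) relative to recording start; acceleration
#' in g. With `iso8601 = TRUE` the timestamp column may instead hold
#' ISO-8601 date-times, converted to seconds from the first sample.
#'
#' @param path CSV file path.
#' @param participant_id,visit_id Identifiers to attach.
#' @param declared_rate_hz Declared sampling rate (30, 80 or 100); checked
#'   against the observed median sample spacing (1% tolerance).
#' @param iso8601 Accept ISO-8601 timestamps.
#' @return A [raw_recording()].
#' @export
read_raw_recording <- function(path, declared_rate_hz,
                               participant_id = NA, visit_id = NA,
                               iso8601 = FALSE) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_input("missing column(s): ", paste(miss, collapse = ", "))
  }
  ts <- d$timestamp
  if (iso8601) {
    tt <- as.POSIXct(ts, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
    if (anyNA(tt)) stop_input("unparseable ISO-8601 timestamp")
    ts <- as.numeric(tt) - as.numeric(tt[1])
  }
  if (is.na(participant_id)) {
    participant_id <- sub("\\.csv$", "", basename(path))
  }
  raw_recording(participant_id, visit_id %||% NA, declared_rate_hz,
                ts, d$x, d$y, d$z)
}

#' Write a raw recording in the canonical CSV dialect
#'
#' @param recording A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(recording, path) {
  stopifnot(inherits(recording, "wpa_recording"))
  d <- data.frame(timestamp = format(recording$t, digits = 15, trim = TRUE,
                                     scientific = FALSE),
                  x = recording$x, y = recording$y, z = recording$z)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read activity-interval annotations
#'
#' Expects columns `participant_id, visit_id, activity_name, start_s,
#' end_s, met` (`met` may be empty where calorimetry was invalid).
#' @param path CSV file path.
#' @return Data frame of intervals.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "visit_id", "activity_name",
            "start_s", "end_s", "met")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_input("missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(d$end_s <= d$start_s)) stop_input("intervals must have end_s > start_s")
  d
}

#' Read a participant roster
#'
#' Expects columns `participant_id, age, sex, has_start_end_times,
#' has_sufficient_activity_data, has_demographics, has_valid_ee,
#' visits_attended`.
#' @param path CSV file path.
#' @return Data frame, flags coerced to logical.
#' @export
read_roster <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "sex", "has_start_end_times",
            "has_sufficient_activity_data", "has_demographics",
            "has_valid_ee", "visits_attended")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_input("missing column(s): ", paste(miss, collapse = ", "))
  }
  for (f in grep("^has_", need, value = TRUE)) d[[f]] <- as.logical(d[[f]])
  d
}

# exclusion reasons, evaluated in this fixed order so a participant failing
# several criteria is reported once under the first reason and the counts
# partition the excluded set
.exclusion_reasons <- c(
  has_start_end_times = "missing start/end time of activities",
  has_sufficient_activity_data = "insufficient length of activity or missing values",
  has_demographics = "missing demographic information"
)

#' Apply the cohort exclusion filters
#'
#' A participant is excluded when any of the three eligibility flags
#' (start/end times recorded, sufficient activity data, demographics
#' complete) is false; the first failing flag, in that order, is recorded
#' as the exclusion reason.
#'
#' @param roster Roster data frame (see [read_roster()]).
#' @return List with elements `included` (roster subset) and `excluded`
#'   (roster subset with an extra `reason` column).
#' @export
apply_exclusions <- function(roster) {
  flags <- names(.exclusion_reasons)
  if (nrow(roster) == 0) {
    excl <- roster
    excl$reason <- character(0)
    return(list(included = roster, excluded = excl))
  }
  reason <- rep(NA_character_, nrow(roster))
  for (f in rev(flags)) {
    reason[!roster[[f]]] <- .exclusion_reasons[[f]]
  }
  excl <- roster[!is.na(reason), , drop = FALSE]
  excl$reason <- reason[!is.na(reason)]
  list(included = roster[is.na(reason), , drop = FALSE], excluded = excl)
}

#' Restrict to participants with valid energy-expenditure data
#'
#' @param included Exclusion-filtered roster.
#' @return Roster subset with `has_valid_ee` true.
#' @export
ee_eligible <- function(included) {
  included[included$has_valid_ee %in% TRUE, , drop = FALSE]
}

#' Total number of data-collection visits
#'
#' @param roster Roster data frame with a `visits_attended` column.
#' @return Integer sum of visits attended.
#' @export
count_visits <- function(roster) {
  if (nrow(roster) == 0) return(0L)
  if (!all(roster$visits_attended %in% 1:4)) {
    stop_input("visits_attended must be in 1..4")
  }
  as.integer(sum(roster$visits_attended))
}
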