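# Exclusion and transformation rules: short-record participants are dropped,
# walking is reduced to maximal >=60 steps/min runs of >=5 consecutive
# minutes, and minutes are rolled up to hourly ACTIVE/INACTIVE/MISSING
# states on a day-granular missingness model.

#' Drop participants with too few recorded days
#'
#' A participant is retained iff the number of distinct calendar days with at
#' least one recorded minute is `>= min_days`.
#'
#' @param cohort a `step_cohort` or list of `minute_step_series`.
#' @param min_days retention threshold in days (default 10).
#' @return `list(retained = cohort subset, excluded_ids = character)`.
#' @export
exclude_short_participants <- function(cohort, min_days = 10L) {
  if (length(cohort) == 0L) config_error("cohort is empty")
  stopifnot(min_days >= 1L)
  ndays <- vapply(cohort, function(s) {
    if (nrow(s) == 0L) 0L else length(unique(as.Date(s$timestamp, tz = "UTC")))
  }, integer(1))
  keep <- ndays >= min_days
  ids <- vapply(cohort, function(s) {
    if (nrow(s) > 0L) s$participant_id[1L] else NA_character_
  }, character(1))
  ids[is.na(ids)] <- names(cohort)[is.na(ids)] %||% "unknown"
  retained <- cohort[keep]
  attr(retained, "config") <- attr(cohort, "config")
  class(retained) <- class(cohort)
  list(retained = retained, excluded_ids = unname(ids[!keep]))
}

#' Detect walk bouts in a minute step series
#'
#' A walk bout is a maximal run of consecutive minutes (timestamps differing
#' by exactly one minute) each with `steps >= min_spm`, of length
#' `>= min_len`. Any timestamp gap or sub-threshold minute breaks a run.
#'
#' @param series a `minute_step_series`.
#' @param min_spm cadence threshold in steps/min (default 60).
#' @param min_len minimum bout length in minutes (default 5).
#' @return a `data.frame` with columns `participant_id`, `start` (POSIXct)
#'   and `duration_min`, ordered by `start`.
#' @export
detect_bouts <- function(series, min_spm = 60L, min_len = 5L) {
  empty <- data.frame(participant_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      duration_min = integer(0))
  if (nrow(series) == 0L) return(empty)
  fast <- series$steps >= min_spm
  if (!any(fast)) return(empty)
  m <- as.numeric(series$timestamp) %/% 60
  mf <- m[fast]
  run_id <- cumsum(c(1, diff(mf) != 1))
  len <- tabulate(run_id)
  starts <- mf[!duplicated(run_id)]
  keep <- len >= min_len
  if (!any(keep)) return(empty)
  data.frame(
    participant_id = series$participant_id[1L],
    start = as.POSIXct(starts[keep] * 60, origin = "1970-01-01", tz = "UTC"),
    duration_min = as.integer(len[keep])
  )
}

#' Reduce a minute series to hourly walking states
#'
#' Every clock hour from the first recorded day's midnight through the last
#' recorded day's 23:00 receives exactly one state: `MISSING` if the hour's
#' calendar day has no records at all, else `ACTIVE` if at least one
#' walk-bout minute falls inside the hour (a bout spanning an hour boundary
#' marks both hours), else `INACTIVE`.
#'
#' @param series a `minute_step_series`.
#' @param bouts the result of [detect_bouts()] on the same series; detected
#'   internally when omitted.
#' @return a `data.frame` with columns `participant_id`, `hour` (POSIXct)
#'   and `state` (`"ACTIVE"`, `"INACTIVE"`, `"MISSING"`).
#' @export
hourly_states <- function(series, bouts = NULL) {
  if (nrow(series) == 0L) {
    return(data.frame(participant_id = character(0),
                      hour = as.POSIXct(character(0), tz = "UTC"),
                      state = character(0)))
  }
  if (is.null(bouts)) bouts <- detect_bouts(series)
  day <- as.Date(series$timestamp, tz = "UTC")
  days <- seq(min(day), max(day), by = "day")
  recorded <- days %in% unique(day)
  hour0 <- as.POSIXct(paste(days[1L], "00:00:00"), tz = "UTC")
  n_hours <- length(days) * 24L
  state <- rep.int("INACTIVE", n_hours)
  state[rep(!recorded, each = 24L)] <- "MISSING"
  if (nrow(bouts) > 0L) {
    bout_minutes <- unlist(lapply(seq_len(nrow(bouts)), function(b) {
      as.numeric(bouts$start[b]) %/% 60 + seq_len(bouts$duration_min[b]) - 1
    }))
    in_series <- bout_minutes %in% (as.numeric(series$timestamp) %/% 60)
    covered <- series$steps[match(bout_minutes[in_series],
                                  as.numeric(series$timestamp) %/% 60)] >= 60
    if (!all(in_series) ) {
      stop("bouts are inconsistent with the series: bout minutes absent from records")
    }
    hr_idx <- unique((bout_minutes %/% 60) - as.numeric(hour0) %/% 3600) + 1L
    if (any(hr_idx < 1L | hr_idx > n_hours)) {
      stop("bouts are inconsistent with the series: outside the recorded span")
    }
    state[hr_idx] <- "ACTIVE"
  }
  data.frame(
    participant_id = series$participant_id[1L],
    hour = hour0 + (seq_len(n_hours) - 1L) * 3600,
    state = state
  )
}

#' Run the full preprocessing stage on a cohort
#'
#' Applies [exclude_short_participants()], then [detect_bouts()] and
#' [hourly_states()] per retained participant.
#'
#' @param cohort a `step_cohort`.
#' @param min_days exclusion threshold (default 10 recorded days).
#' @param min_spm,min_len walk-bout definition.
#' @return `list(states, bouts, excluded_ids)` where `states` and `bouts`
#'   are row-bound data frames across retained participants.
#' @export
preprocess_cohort <- function(cohort, min_days = 10L, min_spm = 60L, min_len = 5L) {
  excl <- exclude_short_participants(cohort, min_days = min_days)
  bouts <- lapply(excl$retained, detect_bouts, min_spm = min_spm, min_len = min_len)
  states <- Map(hourly_states, excl$retained, bouts)
  list(
    states = do.call(rbind, c(states, list(make.row.names = FALSE))),
    bouts = do.call(rbind, c(bouts, list(make.row.names = FALSE))),
    excluded_ids = excl$excluded_ids
  )
}
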