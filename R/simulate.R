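# Synthetic minute-level step streams.
#
# The generator emulates the structure of a step-triggered wrist wearable:
# a minute is recorded only if at least one step was taken, whole calendar
# days drop out when the device is not worn, and walking appears as runs of
# consecutive minutes at walking cadence (>= 60 steps/min).

draw_bout_durations <- function(n, spec) {
  if (n == 0L) return(integer(0))
  x <- round(stats::rlnorm(n, spec$meanlog, spec$sdlog))
  pmax(as.integer(spec$floor %||% 5), as.integer(x))
}

draw_active_cadence <- function(n, spec) {
  spec$min + stats::rpois(n, spec$lambda)
}

draw_background_cadence <- function(n, spec) {
  if (n == 0L) return(integer(0))
  # geometric truncated to [min, max]
  k <- spec$max - spec$min + 1L
  p <- stats::dgeom(0:(k - 1L), spec$prob)
  spec$min + sample.int(k, n, replace = TRUE, prob = p) - 1L
}

#' Simulate one participant's minute-resolution step stream
#'
#' For each non-missing calendar day, walk-bout starts are drawn per
#' hour-of-week as Poisson counts with mean given by the config's
#' `hourly_bout_rate` cell, placed at uniform minutes within the hour;
#' each bout writes consecutive minutes at walking cadence (overlapping
#' bouts merge; bouts are truncated at midnight). Recorded non-bout minutes
#' are sprinkled through the waking window at sub-walking cadence. Missing
#' days contribute no records at all. The stream is fully reproducible from
#' `(config$seed, participant_index)`.
#'
#' @param config a [generator_config()].
#' @param participant_index 1-based index in `1:n_participants`.
#' @return a `minute_step_series`: a `data.frame` with columns
#'   `participant_id`, `timestamp` (POSIXct, UTC, minute resolution,
#'   strictly increasing) and `steps` (positive integer).
#' @export
simulate_participant <- function(config, participant_index) {
  stopifnot(inherits(config, "generator_config"))
  if (participant_index < 1L || participant_index > config$n_participants) {
    config_error("participant_index must be in 1..n_participants")
  }
  pid <- sprintf("P%03d", participant_index)
  origin <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  # Monday = 1 ... Sunday = 7 for the rate matrix columns
  dow0 <- as.integer(format(config$start_date, "%u"))

  with_seed(child_seed(config$seed, participant_index), {
    missing_day <- stats::runif(config$n_days) < config$missing_day_prob
    minute_idx <- integer(0)  # absolute minute since origin
    steps <- integer(0)
    for (d in seq_len(config$n_days)) {
      if (missing_day[d]) next
      dow <- ((dow0 - 1L + d - 1L) %% 7L) + 1L
      rates <- config$hourly_bout_rate[, dow]
      n_starts <- stats::rpois(24L, rates)
      bout_min <- integer(0)   # minute-of-day indices 0..1439 inside bouts
      if (sum(n_starts) > 0L) {
        start_hour <- rep.int(0:23, n_starts)
        start_min <- start_hour * 60L + sample.int(60L, sum(n_starts), replace = TRUE) - 1L
        dur <- draw_bout_durations(length(start_min), config$bout_duration)
        bout_min <- unique(unlist(lapply(seq_along(start_min), function(b) {
          seq.int(start_min[b], min(start_min[b] + dur[b] - 1L, 1439L))
        })))
      }
      n_bg <- stats::rpois(1L, config$background_minutes_per_day)
      window <- setdiff(
        as.vector(outer(0:59, config$background_window_hours * 60L, `+`)),
        bout_min
      )
      bg_min <- if (n_bg > 0L && length(window) > 0L) {
        sort(sample(window, min(n_bg, length(window))))
      } else integer(0)
      day_min <- sort(c(bout_min, bg_min))
      day_steps <- integer(length(day_min))
      in_bout <- day_min %in% bout_min
      day_steps[in_bout] <- draw_active_cadence(sum(in_bout), config$active_cadence)
      day_steps[!in_bout] <- draw_background_cadence(sum(!in_bout), config$background_cadence)
      minute_idx <- c(minute_idx, (d - 1L) * 1440L + day_min)
      steps <- c(steps, day_steps)
    }
    structure(
      data.frame(
        participant_id = rep.int(pid, length(minute_idx)),
        timestamp = origin + minute_idx * 60,
        steps = as.integer(steps),
        stringsAsFactors = FALSE
      ),
      class = c("minute_step_series", "data.frame")
    )
  })
}

#' Simulate a cohort of participants
#'
#' @param config a [generator_config()].
#' @return a `step_cohort`: a named list of `minute_step_series`, one per
#'   participant, with the config attached as attribute `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cohort <- lapply(seq_len(config$n_participants), function(i) {
    simulate_participant(config, i)
  })
  names(cohort) <- vapply(seq_len(config$n_participants),
                          function(i) sprintf("P%03d", i), character(1))
  structure(cohort, config = config, class = "step_cohort")
}

#' Per-participant and cohort-level data summary
#'
#' Computes, per participant: days with any data, recorded minutes/day,
#' minutes/day at or above the walking cadence threshold, detected walk
#' bouts/day, mean bout length, walking (bout-containing) hours/day, and the
#' fraction of study days that are wholly missing (denominator: the
#' first-to-last recorded-day span). Cohort rows report the mean and SD of
#' each statistic across participants.
#'
#' @param cohort a `step_cohort` or plain list of `minute_step_series`.
#' @param min_spm,min_len walk-bout definition passed to [detect_bouts()].
#' @return a `data.frame` with columns `statistic`, `mean`, `sd`.
#' @export
summarize_cohort <- function(cohort, min_spm = 60L, min_len = 5L) {
  cohort <- cohort[vapply(cohort, nrow, integer(1)) >= 0]  # keep empties
  if (length(cohort) == 0L) config_error("cannot summarize an empty cohort")
  per <- lapply(cohort, function(series) {
    if (nrow(series) == 0L) {
      return(data.frame(days_with_data = 0, recorded_min_per_day = NA_real_,
                        walk_min_per_day = NA_real_, bouts_per_day = NA_real_,
                        mean_bout_length_min = NA_real_,
                        walking_hours_per_day = NA_real_,
                        missing_day_fraction = 1))
    }
    day <- as.Date(series$timestamp, tz = "UTC")
    ndays <- length(unique(day))
    span <- as.integer(max(day) - min(day)) + 1L
    bouts <- detect_bouts(series, min_spm = min_spm, min_len = min_len)
    walk_hours <- if (nrow(bouts) > 0L) {
      length(unique(unlist(lapply(seq_len(nrow(bouts)), function(b) {
        mins <- bouts$start[b] + (seq_len(bouts$duration_min[b]) - 1L) * 60
        unique(as.numeric(mins) %/% 3600)
      }))))
    } else 0L
    data.frame(
      days_with_data = ndays,
      recorded_min_per_day = nrow(series) / ndays,
      walk_min_per_day = sum(series$steps >= min_spm) / ndays,
      bouts_per_day = nrow(bouts) / ndays,
      mean_bout_length_min = if (nrow(bouts)) mean(bouts$duration_min) else NA_real_,
      walking_hours_per_day = walk_hours / ndays,
      missing_day_fraction = (span - ndays) / span
    )
  })
  per <- do.call(rbind, per)
  data.frame(
    statistic = names(per),
    mean = vapply(per, function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(per, function(x) stats::sd(x, na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
}
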