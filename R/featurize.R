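# One-hot predictor construction. Each instance is anchored at a
# participant-hour: four calendar one-hot blocks describe the anchor itself,
# and 840 lag-hour triples (ACTIVE/INACTIVE/MISSING) describe the 5 prior
# weeks of hourly walking. The binary outcome is whether any of the next
# `horizon` hours (anchor inclusive) is ACTIVE.

N_TIME_FEATURES <- 24L + 7L + 12L + 31L          # hour, dow, month, day-of-month
N_LAG_HOURS <- 840L                              # 5 weeks x 168 h
N_FEATURES <- N_TIME_FEATURES + 3L * N_LAG_HOURS # 2,594
STATE_LEVELS <- c("ACTIVE", "INACTIVE", "MISSING")

#' Describe the feature-vector layout
#'
#' @return a list with the block names, offsets and widths of the
#'   2,594-column binary layout: hour-of-day (24), day-of-week (7, Monday
#'   first), month (12), day-of-month (31), then 840 lag-hour triples in
#'   state order ACTIVE, INACTIVE, MISSING (lag 1 first).
#' @export
feature_layout <- function() {
  list(
    n_features = N_FEATURES,
    blocks = data.frame(
      block = c("hour_of_day", "day_of_week", "month", "day_of_month", "lag_history"),
      offset = c(0L, 24L, 31L, 43L, N_TIME_FEATURES),
      width = c(24L, 7L, 12L, 31L, 3L * N_LAG_HOURS)
    ),
    lag_hours = N_LAG_HOURS,
    state_order = STATE_LEVELS
  )
}

#' One-hot encode the calendar position of an anchor hour
#'
#' @param anchor POSIXct hour timestamp(s), UTC.
#' @return for a single anchor, a binary vector of length 74; for several, a
#'   matrix with one row per anchor. Blocks: hour-of-day 0-23, day-of-week
#'   Monday-Sunday, month 1-12, day-of-month 1-31.
#' @export
encode_time <- function(anchor) {
  lt <- as.POSIXlt(anchor, tz = "UTC")
  hour <- lt$hour
  dow <- ((lt$wday + 6L) %% 7L)            # Monday = 0
  month <- lt$mon
  dom <- lt$mday - 1L
  n <- length(hour)
  m <- matrix(0L, n, N_TIME_FEATURES)
  idx <- cbind(seq_len(n), 1L + c(hour, 24L + dow, 31L + month, 43L + dom))
  m[cbind(rep(seq_len(n), 4L), idx[, 2L])] <- 1L
  if (n == 1L) drop(m) else m
}

# Integer state codes used throughout featurization: ACTIVE 1, INACTIVE 2,
# MISSING 3 (matching STATE_LEVELS).
state_codes <- function(states) {
  code <- match(states, STATE_LEVELS)
  if (anyNA(code)) stop("unknown hourly state; expected ACTIVE/INACTIVE/MISSING")
  code
}

#' One-hot encode the 5-week lag history before an anchor
#'
#' For lag 1..840 the triple for hour `anchor - lag` is the one-hot of its
#' state; hours before the start of the participant's span are encoded
#' MISSING.
#'
#' @param states a single participant's [hourly_states()] table.
#' @param anchor POSIXct hour timestamp.
#' @return a binary vector of length 2,520.
#' @export
encode_history <- function(states, anchor) {
  codes <- state_codes(states$state)
  pos <- as.integer(round((as.numeric(anchor) - as.numeric(states$hour[1L])) / 3600)) + 1L
  lag_pos <- pos - seq_len(N_LAG_HOURS)
  lag_code <- ifelse(lag_pos >= 1L & lag_pos <= length(codes),
                     codes[pmax(lag_pos, 1L)], 3L)
  v <- integer(3L * N_LAG_HOURS)
  v[3L * (seq_len(N_LAG_HOURS) - 1L) + lag_code] <- 1L
  v
}

#' Label the next-`horizon`-hours walking outcome at an anchor
#'
#' The outcome window is `[anchor, anchor + horizon)`; the anchor hour itself
#' is the first predicted hour. Label 1 if any window hour is ACTIVE; 0 if
#' none is ACTIVE and at least one is observed (non-MISSING); `NA` (skip, no
#' instance) if the window extends past the span or all its hours are
#' MISSING.
#'
#' @param states a single participant's [hourly_states()] table.
#' @param anchor POSIXct hour timestamp.
#' @param horizon window length in hours (default 3).
#' @return 1, 0, or `NA` (skip).
#' @export
label_outcome <- function(states, anchor, horizon = 3L) {
  stopifnot(horizon >= 1L)
  codes <- state_codes(states$state)
  pos <- as.integer(round((as.numeric(anchor) - as.numeric(states$hour[1L])) / 3600)) + 1L
  win <- pos + seq_len(horizon) - 1L
  if (any(win < 1L) || any(win > length(codes))) return(NA_integer_)
  w <- codes[win]
  if (any(w == 1L)) return(1L)
  if (all(w == 3L)) return(NA_integer_)
  0L
}

#' Build the instance set for a preprocessed cohort
#'
#' One candidate instance per participant-hour anchor in each participant's
#' span; anchors whose outcome window leaves the span or is wholly MISSING
#' are skipped. Features follow [feature_layout()]: 74 calendar indicators
#' plus 840 lag-state triples, exactly 844 ones per instance.
#'
#' @param states row-bound [hourly_states()] for the cohort.
#' @param horizon outcome window in hours (default 3).
#' @return an `instance_set`: list with sparse binary `features`
#'   (`dgCMatrix`, instances x 2,594), integer `label`, `participant_id`,
#'   `anchor` (POSIXct) and a `provenance` list (horizon, lag hours, counts).
#' @export
build_instances <- function(states, horizon = 3L) {
  if (is.null(states) || nrow(states) == 0L) config_error("no hourly states supplied")
  parts <- split(states, states$participant_id)
  rows_i <- list(); rows_j <- list()
  meta <- list()
  offset <- 0L
  for (pid in names(parts)) {
    st <- parts[[pid]]
    st <- st[order(st$hour), , drop = FALSE]
    codes <- state_codes(st$state)
    H <- length(codes)
    if (H < horizon) next
    a_idx <- seq_len(H - horizon + 1L)
    # window labels, vectorized over anchors
    any_active <- rep(FALSE, length(a_idx)); all_missing <- rep(TRUE, length(a_idx))
    for (k in seq_len(horizon) - 1L) {
      wk <- codes[a_idx + k]
      any_active <- any_active | wk == 1L
      all_missing <- all_missing & wk == 3L
    }
    keep <- !( !any_active & all_missing )
    a_idx <- a_idx[keep]
    if (length(a_idx) == 0L) next
    label <- ifelse(any_active[keep], 1L, 0L)
    n_a <- length(a_idx)
    # calendar block columns (4 ones per anchor)
    anchors <- st$hour[a_idx]
    lt <- as.POSIXlt(anchors, tz = "UTC")
    time_j <- cbind(1L + lt$hour,
                    25L + ((lt$wday + 6L) %% 7L),
                    32L + lt$mon,
                    44L + lt$mday - 1L)
    # lag-history columns (840 ones per anchor)
    lag_pos <- outer(a_idx, seq_len(N_LAG_HOURS), `-`)       # n_a x 840
    lag_code <- matrix(3L, n_a, N_LAG_HOURS)
    inside <- lag_pos >= 1L
    lag_code[inside] <- codes[lag_pos[inside]]
    hist_j <- N_TIME_FEATURES + 3L * (col(lag_code) - 1L) + lag_code
    rows_i[[pid]] <- c(rep(offset + seq_len(n_a), 4L), rep(offset + seq_len(n_a), N_LAG_HOURS))
    rows_j[[pid]] <- c(as.vector(time_j), as.vector(hist_j))
    meta[[pid]] <- data.frame(participant_id = pid, anchor = anchors, label = label)
    offset <- offset + n_a
  }
  if (offset == 0L) config_error("no instances could be built (empty or too-short spans)")
  meta <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  features <- Matrix::sparseMatrix(
    i = unlist(rows_i, use.names = FALSE),
    j = unlist(rows_j, use.names = FALSE),
    x = 1,
    dims = c(offset, N_FEATURES)
  )
  new_instance_set(features, meta$label, meta$participant_id, meta$anchor,
                   provenance = list(horizon = as.integer(horizon),
                                     lag_hours = N_LAG_HOURS,
                                     n_instances = offset,
                                     n_active = sum(meta$label == 1L),
                                     n_inactive = sum(meta$label == 0L)))
}

new_instance_set <- function(features, label, participant_id, anchor, provenance) {
  stopifnot(nrow(features) == length(label))
  if (anyDuplicated(paste(participant_id, as.numeric(anchor)))) {
    stop("duplicate (participant, anchor) pairs in instance set")
  }
  structure(list(features = features, label = as.integer(label),
                 participant_id = participant_id, anchor = anchor,
                 provenance = provenance),
            class = "instance_set")
}

#' Subset an instance set by row indices
#' @param x an `instance_set`.
#' @param idx integer row indices.
#' @return the subset `instance_set` (provenance carried over).
#' @export
subset_instances <- function(x, idx) {
  stopifnot(inherits(x, "instance_set"))
  new_instance_set(x$features[idx, , drop = FALSE], x$label[idx],
                   x$participant_id[idx], x$anchor[idx], x$provenance)
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("<instance_set> %d instances x %d features; %d active / %d inactive\n",
              nrow(x$features), ncol(x$features),
              sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}
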