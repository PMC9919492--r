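# Shared fixtures and independent oracles, all built in code.

UTC0 <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")

# A minute series with `steps[i]` at consecutive minutes from `start`;
# entries that are NA are dropped (timestamp gaps).
make_series <- function(steps, start = UTC0, pid = "P001") {
  keep <- which(!is.na(steps))
  structure(
    data.frame(participant_id = rep_len(pid, length(keep)),
               timestamp = start + (keep - 1L) * 60,
               steps = as.integer(steps[keep])),
    class = c("minute_step_series", "data.frame"))
}

# Brute-force walk-bout oracle: tests every (start, length) pair for the
# cadence, length and maximality conditions over a minute-occupancy lookup.
brute_bouts <- function(series, min_spm = 60, min_len = 5) {
  if (nrow(series) == 0L) return(data.frame(start = numeric(0), duration = integer(0)))
  m <- as.numeric(series$timestamp) %/% 60
  lo <- min(m) - 1; hi <- max(m) + 1
  fastset <- rep(FALSE, hi - lo + 1L)
  fastset[m[series$steps >= min_spm] - lo + 1L] <- TRUE
  at <- function(minute) {
    i <- minute - lo + 1L
    i >= 1L & i <= length(fastset) & fastset[pmax(pmin(i, length(fastset)), 1L)]
  }
  out <- NULL
  for (i in seq_along(m)) {
    for (L in seq.int(min_len, length(m))) {
      mins <- m[i] + 0:(L - 1L)
      if (all(at(mins)) && !at(m[i] - 1) && !at(m[i] + L)) {
        out <- rbind(out, data.frame(start = m[i], duration = L))
      }
    }
  }
  if (is.null(out)) data.frame(start = numeric(0), duration = integer(0)) else
    out[order(out$start), , drop = FALSE]
}

# Independent enumeration oracle for instance labels: scans every anchor of
# a single participant's state vector with explicit loops.
enum_instances <- function(state_chr, horizon = 3L) {
  H <- length(state_chr)
  labels <- integer(0); anchors <- integer(0)
  for (a in seq_len(H)) {
    if (a + horizon - 1L > H) next
    win <- state_chr[a:(a + horizon - 1L)]
    if (any(win == "ACTIVE")) {
      labels <- c(labels, 1L); anchors <- c(anchors, a)
    } else if (!all(win == "MISSING")) {
      labels <- c(labels, 0L); anchors <- c(anchors, a)
    }
  }
  list(anchors = anchors, labels = labels)
}

# States table for one participant over `n_hours` hours from UTC0.
make_states <- function(state_chr, pid = "P001", start = UTC0) {
  data.frame(participant_id = pid,
             hour = start + (seq_along(state_chr) - 1L) * 3600,
             state = state_chr)
}

# Small structured cohort reused by model/search tests (built once per run).
small_structured_instances <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_preset("structured", n_participants = 6, n_days = 14, seed = 301)
      pre <- preprocess_cohort(simulate_cohort(cfg), min_days = 5)
      cache <<- build_instances(pre$states)
    }
    cache
  }
})
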