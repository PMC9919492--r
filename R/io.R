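# Delimited-text readers/writers for every pipeline artifact. All files are
# plain text so runs are diffable and byte-reproducible.

#' Write / read a cohort of minute step series
#'
#' One CSV per cohort with columns `participant_id,timestamp,steps`;
#' timestamps are ISO-8601 UTC at minute resolution.
#'
#' @param cohort a `step_cohort` or list of `minute_step_series`.
#' @param path CSV file path.
#' @return the path (writer, invisibly); a `step_cohort` (reader).
#' @export
write_cohort <- function(cohort, path) {
  df <- do.call(rbind, c(unname(lapply(cohort, as.data.frame)),
                         list(make.row.names = FALSE)))
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = "participant_id", integer = "steps")))
  if (nrow(df) == 0L) {
    return(structure(list(), class = "step_cohort"))
  }
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  parts <- split(df, df$participant_id)
  cohort <- lapply(parts, function(p) {
    p <- p[order(p$timestamp), , drop = FALSE]
    rownames(p) <- NULL
    class(p) <- c("minute_step_series", "data.frame")
    p
  })
  structure(cohort, class = "step_cohort")
}

#' Write / read an hourly state table
#'
#' CSV with columns `participant_id,hour,state`.
#'
#' @param states a row-bound [hourly_states()] data frame.
#' @param path CSV file path.
#' @export
write_states <- function(states, path) {
  out <- states
  out$hour <- format(out$hour, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("participant_id", "state"))))
  df$hour <- as.POSIXct(df$hour, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df
}

#' Persist / load an instance set
#'
#' Written as a directory: `features.mtx` (MatrixMarket sparse text),
#' `meta.csv` (participant, anchor, label per row) and `layout.json` (column
#' layout and provenance). The round trip is exact.
#'
#' @param instances an `instance_set`.
#' @param dir directory to create/fill.
#' @export
write_instances <- function(instances, dir) {
  stopifnot(inherits(instances, "instance_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(instances$features, file.path(dir, "features.mtx"))
  meta <- data.frame(
    participant_id = instances$participant_id,
    anchor = format(instances$anchor, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    label = instances$label)
  data.table::fwrite(meta, file.path(dir, "meta.csv"))
  layout <- feature_layout()
  jsonlite::write_json(
    list(n_features = layout$n_features,
         blocks = layout$blocks,
         state_order = layout$state_order,
         provenance = instances$provenance),
    file.path(dir, "layout.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_instances
#' @export
read_instances <- function(dir) {
  features <- methods::as(Matrix::readMM(file.path(dir, "features.mtx")), "CsparseMatrix")
  features <- methods::as(features, "dMatrix")
  meta <- as.data.frame(data.table::fread(file.path(dir, "meta.csv"),
                                          colClasses = list(character = c("participant_id", "anchor"))))
  layout <- jsonlite::read_json(file.path(dir, "layout.json"), simplifyVector = TRUE)
  new_instance_set(features, as.integer(meta$label), meta$participant_id,
                   as.POSIXct(meta$anchor, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   provenance = layout$provenance)
}
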