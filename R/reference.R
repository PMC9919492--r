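# Published reference results from the original HeartSteps walking-forecast
# analysis, shipped so reported per-algorithm metrics can be recomputed from
# the 10-fold mean confusion matrices and so the study's class-imbalance
# arithmetic is reproducible without the (undeposited) raw data.

#' Reference mean confusion matrices
#'
#' The 10-fold mean confusion matrix reported for each of the six classifier
#' families in the original HeartSteps walking-forecast analysis (test parts
#' of ~1,625 balanced instances per fold). Useful for recomputing the
#' published accuracy/sensitivity/specificity values via
#' [metrics_from_counts()].
#'
#' @return a `data.frame` with columns `algorithm`, `tp_mean`, `tn_mean`,
#'   `fp_mean`, `fn_mean`.
#' @export
reference_confusion <- function() {
  path <- system.file("extdata", "reference_confusion.csv",
                      package = "stepcast", mustWork = TRUE)
  as.data.frame(data.table::fread(path, colClasses = list(character = "algorithm")))
}

#' Reference class counts before balancing
#'
#' The original analysis prepared 8,129 "walking" and 37,711 "non-walking"
#' participant-hour outcomes before undersampling.
#'
#' @return named list `n_active`, `n_inactive`.
#' @export
reference_class_counts <- function() {
  list(n_active = 8129L, n_inactive = 37711L)
}
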