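# Confusion counts and the four performance metrics (accuracy, MCC,
# sensitivity, specificity), plus the K-fold evaluation loop and the
# multi-algorithm comparison report.

#' Confusion counts for a binary prediction
#'
#' Positive class is "walked" (label 1). Counts are stored as reals so that
#' fold-averaged matrices remain representable.
#'
#' @param truth,pred equal-length binary (0/1) vectors, or `tp/tn/fp/fn`
#'   given directly to [confusion_counts()].
#' @return a `confusion_counts` object with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  confusion_counts(tp = sum(truth == 1 & pred == 1),
                   tn = sum(truth == 0 & pred == 0),
                   fp = sum(truth == 0 & pred == 1),
                   fn = sum(truth == 1 & pred == 0))
}

#' @rdname confusion
#' @param tp,tn,fp,fn non-negative counts (reals allowed, e.g. fold means).
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. If any marginal
#' sum is zero the coefficient is undefined; by convention 0 is returned
#' with a warning.
#'
#' @param cc a `confusion_counts`.
#' @return a real in `[-1, 1]`.
#' @export
mcc <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  marg <- c(cc$tp + cc$fp, cc$tp + cc$fn, cc$tn + cc$fp, cc$tn + cc$fn)
  if (any(marg == 0)) {
    warning("MCC undefined (zero marginal); returning 0 by convention")
    return(0)
  }
  (cc$tp * cc$tn - cc$fp * cc$fn) / sqrt(prod(marg))
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' @param cc a `confusion_counts`.
#' @return a `metric_set`: named list `accuracy`, `mcc`, `sensitivity`,
#'   `specificity`. A metric with a zero denominator is `NaN`.
#' @export
metrics_from_counts <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total == 0) stop("empty confusion counts")
  m <- list(
    accuracy = (cc$tp + cc$tn) / total,
    mcc = suppressWarnings(mcc(cc)),
    sensitivity = cc$tp / (cc$tp + cc$fn),
    specificity = cc$tn / (cc$tn + cc$fp)
  )
  structure(m, class = "metric_set")
}

#' Evaluate one classifier spec across precomputed folds
#'
#' For each fold: fit on the train part (the tune part steers early stopping
#' for the MLP and is recorded otherwise), predict the test part, and tally
#' confusion counts. Aggregates are the arithmetic mean and sample SD
#' (denominator K-1) across folds, plus the mean confusion matrix and mean
#' fit wall-clock.
#'
#' @param instances a balanced `instance_set`.
#' @param folds a `fold_splits` over the same instances.
#' @param spec a [classifier_spec()].
#' @return a `kfold_result`: per-fold `metrics` (data.frame), `confusion`
#'   list, `mean_confusion`, `summary` (mean/sd per metric), `mean_fit_seconds`.
#' @export
run_kfold <- function(instances, folds, spec) {
  stopifnot(inherits(instances, "instance_set"), inherits(folds, "fold_splits"))
  per_fold <- lapply(folds, function(fold) {
    fitted <- fit_with_tuning(build_classifier(spec),
                              instances$features[fold$train_ids, , drop = FALSE],
                              instances$label[fold$train_ids],
                              instances$features[fold$tune_ids, , drop = FALSE],
                              instances$label[fold$tune_ids])
    truth <- instances$label[fold$test_ids]
    pred <- predict_labels(fitted, instances$features[fold$test_ids, , drop = FALSE])
    if (length(unique(truth)) < 2L) {
      warning(sprintf("fold %d has a single-class test set", fold$fold_index))
    }
    cc <- confusion(truth, pred)
    list(counts = cc, metrics = metrics_from_counts(cc),
         seconds = fitted$report$seconds)
  })
  metric_names <- c("accuracy", "mcc", "sensitivity", "specificity")
  tab <- data.frame(fold = seq_along(per_fold))
  for (mn in metric_names) {
    tab[[mn]] <- vapply(per_fold, function(f) f$metrics[[mn]], numeric(1))
  }
  mean_cc <- confusion_counts(
    tp = mean(vapply(per_fold, function(f) f$counts$tp, numeric(1))),
    tn = mean(vapply(per_fold, function(f) f$counts$tn, numeric(1))),
    fp = mean(vapply(per_fold, function(f) f$counts$fp, numeric(1))),
    fn = mean(vapply(per_fold, function(f) f$counts$fn, numeric(1)))
  )
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(mn) mean(tab[[mn]]), numeric(1)),
    sd = vapply(metric_names, function(mn) stats::sd(tab[[mn]]), numeric(1)),
    row.names = NULL
  )
  seconds <- vapply(per_fold, function(f) f$seconds, numeric(1))
  structure(list(spec = spec, metrics = tab,
                 confusion = lapply(per_fold, `[[`, "counts"),
                 mean_confusion = mean_cc,
                 mean_matrix_metrics = metrics_from_counts(mean_cc),
                 summary = summary,
                 fit_seconds = seconds,
                 mean_fit_seconds = mean(seconds)),
            class = "kfold_result")
}

#' Compare several classifier specs on identical folds
#'
#' Every spec is evaluated with [run_kfold()] on the same `fold_splits`, so
#' metric differences reflect the algorithms, not the data split. Produces
#' three report tables: per-algorithm mean (SD) metrics, mean confusion
#' matrices, and a descriptive timing summary (min/max/mean/SD and a
#' mean +/- 1.96 SD interval). Timing is hardware-bound and reported
#' descriptively only.
#'
#' @param instances a balanced `instance_set`.
#' @param folds a `fold_splits`.
#' @param specs named list of [classifier_spec()]s.
#' @return an `algo_comparison`: `results` (named `kfold_result` list) and
#'   data frames `metrics_table`, `confusion_table`, `timing_table`.
#' @export
compare_algorithms <- function(instances, folds, specs) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$kind, character(1))
  }
  results <- lapply(specs, function(spec) run_kfold(instances, folds, spec))
  metrics_table <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    row <- data.frame(algorithm = nm)
    for (k in seq_len(nrow(s))) {
      row[[paste0(s$metric[k], "_mean")]] <- s$mean[k]
      row[[paste0(s$metric[k], "_sd")]] <- s$sd[k]
    }
    row
  }))
  confusion_table <- do.call(rbind, lapply(names(results), function(nm) {
    cc <- results[[nm]]$mean_confusion
    sdof <- function(f) stats::sd(vapply(results[[nm]]$confusion, `[[`, numeric(1), f))
    data.frame(algorithm = nm, tp_mean = cc$tp, tp_sd = sdof("tp"),
               tn_mean = cc$tn, tn_sd = sdof("tn"),
               fp_mean = cc$fp, fp_sd = sdof("fp"),
               fn_mean = cc$fn, fn_sd = sdof("fn"))
  }))
  timing_table <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$fit_seconds
    data.frame(algorithm = nm, min = min(s), max = max(s), mean = mean(s),
               sd = stats::sd(s),
               ci_low = mean(s) - 1.96 * stats::sd(s),
               ci_high = mean(s) + 1.96 * stats::sd(s))
  }))
  structure(list(results = results, metrics_table = metrics_table,
                 confusion_table = confusion_table, timing_table = timing_table),
            class = "algo_comparison")
}
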