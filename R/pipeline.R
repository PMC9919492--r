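# End-to-end orchestration: each stage reads its predecessor's on-disk
# artifact and writes its own, so a run is resumable, inspectable and -- with
# timing segregated into its own files -- byte-reproducible.

#' Configuration for a full pipeline run
#'
#' @param out_dir output directory (created if needed).
#' @param preset generator preset name (see [generator_preset()]).
#' @param n_participants,n_days optional generator overrides.
#' @param seed master seed; the simulate/balance/fold/search stages use
#'   [child_seed()] streams 1-4 of it.
#' @param min_days participant exclusion threshold (recorded days).
#' @param min_spm,min_len walk-bout definition.
#' @param horizon outcome window in hours.
#' @param K number of folds.
#' @param algorithms classifier kinds to evaluate (default: the six
#'   families, with a small default MLP architecture).
#' @param hyperparams named list of per-kind hyperparameter lists.
#' @param mlp_hidden hidden-layer widths for the fixed "mlp" entry in
#'   `algorithms`.
#' @param n_trials,max_layers,width_choices architecture search settings
#'   (the search stage).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       preset = "default",
                       n_participants = NULL,
                       n_days = NULL,
                       seed = 1L,
                       min_days = 10L, min_spm = 60L, min_len = 5L,
                       horizon = 3L, K = 10L,
                       algorithms = c("logistic_regression", "rbf_svm",
                                      "gradient_boosted_trees", "mlp",
                                      "decision_tree", "random_forest"),
                       hyperparams = list(),
                       mlp_hidden = c(32L, 16L),
                       n_trials = 90L, max_layers = 5L,
                       width_choices = c(4L, 8L, 16L, 32L, 64L, 128L, 256L)) {
  structure(list(out_dir = out_dir, preset = preset,
                 n_participants = n_participants, n_days = n_days,
                 seed = as.integer(seed), min_days = min_days,
                 min_spm = min_spm, min_len = min_len,
                 horizon = horizon, K = K, algorithms = algorithms,
                 hyperparams = hyperparams, mlp_hidden = mlp_hidden,
                 n_trials = n_trials, max_layers = max_layers,
                 width_choices = width_choices),
            class = "run_config")
}

pipeline_paths <- function(config) {
  d <- config$out_dir
  list(config = file.path(d, "run_config.json"),
       cohort = file.path(d, "cohort.csv"),
       states = file.path(d, "states.csv"),
       exclusions = file.path(d, "exclusions.json"),
       instances = file.path(d, "instances"),
       balance = file.path(d, "balance.json"),
       folds = file.path(d, "folds.json"),
       fold_metrics = file.path(d, "fold_metrics.csv"),
       timing = file.path(d, "timing.csv"),
       search_log = file.path(d, "search_log.json"),
       search_timing = file.path(d, "search_timing.csv"),
       table_metrics = file.path(d, "table_metrics.csv"),
       table_confusion = file.path(d, "table_confusion.csv"),
       table_timing = file.path(d, "table_timing.csv"))
}

needs <- function(path, stage, prerequisite) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s' needs '%s'; run the '%s' stage first",
                 stage, path, prerequisite), call. = FALSE)
  }
  path
}

build_generator <- function(config) {
  overrides <- list(seed = child_seed(config$seed, 1L))
  if (!is.null(config$n_participants)) overrides$n_participants <- config$n_participants
  if (!is.null(config$n_days)) overrides$n_days <- config$n_days
  do.call(generator_preset, c(list(name = config$preset), overrides))
}

default_specs <- function(config) {
  specs <- list()
  for (k in seq_along(config$algorithms)) {
    kind <- config$algorithms[k]
    hp <- config$hyperparams[[kind]] %||% list()
    specs[[kind]] <- classifier_spec(
      kind, hyperparams = hp,
      architecture = if (kind == "mlp") architecture_spec(config$mlp_hidden),
      seed = child_seed(config$seed, 100L + k))
  }
  specs
}

#' Run the forecasting pipeline
#'
#' Stages (in order): `simulate` (synthetic cohort CSV), `preprocess`
#' (hourly state table + exclusion log), `featurize` (instance matrix),
#' `evaluate` (balance, folds, per-fold metrics for every configured
#' algorithm), `search` (MLP architecture random search), `report`
#' (mean/SD metric, confusion and timing tables). `"all"` chains every
#' stage. Reruns with an identical config are byte-identical except for the
#' `*timing*` files.
#'
#' @param config a [run_config()].
#' @param stages character vector of stage names, or `"all"`.
#' @return the path list of artifacts, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "preprocess", "featurize", "evaluate", "search", "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  p <- pipeline_paths(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  snapshot <- config
  snapshot$out_dir <- NULL
  jsonlite::write_json(unclass(snapshot), p$config, auto_unbox = TRUE, digits = NA)

  if ("simulate" %in% stages) {
    gen <- build_generator(config)
    write_cohort(simulate_cohort(gen), p$cohort)
    message(sprintf("simulate: %d participants x %d days -> %s",
                    gen$n_participants, gen$n_days, p$cohort))
  }
  if ("preprocess" %in% stages) {
    cohort <- read_cohort(needs(p$cohort, "preprocess", "simulate"))
    pre <- preprocess_cohort(cohort, min_days = config$min_days,
                             min_spm = config$min_spm, min_len = config$min_len)
    write_states(pre$states, p$states)
    jsonlite::write_json(
      list(excluded_ids = pre$excluded_ids,
           n_retained = length(unique(pre$states$participant_id)),
           n_bouts = nrow(pre$bouts)),
      p$exclusions, auto_unbox = TRUE)
    message(sprintf("preprocess: %d retained, %d excluded, %d bouts",
                    length(unique(pre$states$participant_id)),
                    length(pre$excluded_ids), nrow(pre$bouts)))
  }
  if ("featurize" %in% stages) {
    states <- read_states(needs(p$states, "featurize", "preprocess"))
    inst <- build_instances(states, horizon = config$horizon)
    write_instances(inst, p$instances)
    message(sprintf("featurize: %d instances (%d active / %d inactive)",
                    inst$provenance$n_instances, inst$provenance$n_active,
                    inst$provenance$n_inactive))
  }
  if ("evaluate" %in% stages || "search" %in% stages) {
    needs(file.path(p$instances, "meta.csv"), "evaluate", "featurize")
    inst <- read_instances(p$instances)
    balanced <- undersample_balance(inst, seed = child_seed(config$seed, 2L))
    folds <- shuffle_and_fold(balanced, K = config$K,
                              seed = child_seed(config$seed, 3L))
    jsonlite::write_json(balanced$provenance$balance, p$balance, auto_unbox = TRUE)
    write_fold_manifest(folds, p$folds)
  }
  if ("evaluate" %in% stages) {
    cmp <- compare_algorithms(balanced, folds, default_specs(config))
    fold_rows <- do.call(rbind, lapply(names(cmp$results), function(nm) {
      r <- cmp$results[[nm]]
      cbind(data.frame(algorithm = nm), r$metrics,
            tp = vapply(r$confusion, `[[`, numeric(1), "tp"),
            tn = vapply(r$confusion, `[[`, numeric(1), "tn"),
            fp = vapply(r$confusion, `[[`, numeric(1), "fp"),
            fn = vapply(r$confusion, `[[`, numeric(1), "fn"))
    }))
    data.table::fwrite(fold_rows, p$fold_metrics)
    timing <- do.call(rbind, lapply(names(cmp$results), function(nm) {
      data.frame(algorithm = nm, fold = seq_along(cmp$results[[nm]]$fit_seconds),
                 seconds = cmp$results[[nm]]$fit_seconds)
    }))
    data.table::fwrite(timing, p$timing)
    message(sprintf("evaluate: %d algorithms x %d folds on %d balanced instances",
                    length(cmp$results), config$K, nrow(balanced$features)))
  }
  if ("search" %in% stages) {
    space <- search_space(max_layers = config$max_layers,
                          width_choices = config$width_choices,
                          n_trials = config$n_trials,
                          seed = child_seed(config$seed, 4L))
    hp <- config$hyperparams[["mlp"]] %||% list()
    sr <- random_search(balanced, folds, space, hyperparams = hp)
    log_tab <- sr$trials[setdiff(names(sr$trials), "wall_clock_s")]
    jsonlite::write_json(
      list(space = unclass(space), trials = log_tab, top = sr$top),
      p$search_log, auto_unbox = TRUE, digits = NA)
    data.table::fwrite(sr$trials[c("trial", "architecture", "wall_clock_s")],
                       p$search_timing)
    message(sprintf("search: %d trials, best accuracy %.3f (architecture %s)",
                    nrow(sr$trials), max(sr$trials$accuracy_mean),
                    sr$trials$architecture[sr$top[1L]]))
  }
  if ("report" %in% stages) {
    fm <- as.data.frame(data.table::fread(
      needs(p$fold_metrics, "report", "evaluate"),
      colClasses = list(character = "algorithm")))
    agg <- function(f) {
      do.call(rbind, lapply(split(fm, fm$algorithm)[unique(fm$algorithm)], f))
    }
    metrics_tab <- agg(function(g) {
      cc <- confusion_counts(mean(g$tp), mean(g$tn), mean(g$fp), mean(g$fn))
      mm <- metrics_from_counts(cc)
      data.frame(algorithm = g$algorithm[1L],
                 accuracy_mean = mean(g$accuracy), accuracy_sd = stats::sd(g$accuracy),
                 mcc_mean = mean(g$mcc), mcc_sd = stats::sd(g$mcc),
                 sensitivity_mean = mean(g$sensitivity), sensitivity_sd = stats::sd(g$sensitivity),
                 specificity_mean = mean(g$specificity), specificity_sd = stats::sd(g$specificity),
                 accuracy_of_mean_matrix = mm$accuracy,
                 sensitivity_of_mean_matrix = mm$sensitivity,
                 specificity_of_mean_matrix = mm$specificity)
    })
    confusion_tab <- agg(function(g) {
      data.frame(algorithm = g$algorithm[1L],
                 tp_mean = mean(g$tp), tp_sd = stats::sd(g$tp),
                 tn_mean = mean(g$tn), tn_sd = stats::sd(g$tn),
                 fp_mean = mean(g$fp), fp_sd = stats::sd(g$fp),
                 fn_mean = mean(g$fn), fn_sd = stats::sd(g$fn))
    })
    data.table::fwrite(metrics_tab, p$table_metrics)
    data.table::fwrite(confusion_tab, p$table_confusion)
    if (file.exists(p$timing)) {
      tm <- as.data.frame(data.table::fread(p$timing,
                                            colClasses = list(character = "algorithm")))
      timing_tab <- do.call(rbind, lapply(split(tm, tm$algorithm)[unique(tm$algorithm)], function(g) {
        s <- g$seconds
        data.frame(algorithm = g$algorithm[1L], min = min(s), max = max(s),
                   mean = mean(s), sd = stats::sd(s),
                   ci_low = mean(s) - 1.96 * stats::sd(s),
                   ci_high = mean(s) + 1.96 * stats::sd(s))
      }))
      data.table::fwrite(timing_tab, p$table_timing)
    }
    message(sprintf("report: %d algorithm rows -> %s", nrow(metrics_tab),
                    p$table_metrics))
  }
  invisible(p)
}

parse_cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(argv)) stop("missing value for --", key, call. = FALSE)
    opts[[gsub("-", "_", key)]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' `stepcast_main(c("all", "--out", dir, ...))` runs pipeline stages from a
#' shell. Subcommands: `simulate`, `preprocess`, `featurize`, `evaluate`,
#' `search`, `report`, `all`. Flags: `--out` (required), `--preset`,
#' `--seed`, `--participants`, `--days`, `--k`, `--horizon`, `--trials`,
#' `--algorithms` (comma-separated), `--max-layers`.
#'
#' @param argv character vector of command-line arguments.
#' @return 0 on success, invisibly; errors propagate (the installed script
#'   maps them to a nonzero exit status).
#' @export
stepcast_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) < 1L) {
    stop("usage: stepcast <simulate|preprocess|featurize|evaluate|search|report|all> --out DIR [flags]",
         call. = FALSE)
  }
  stage <- argv[1L]
  opts <- parse_cli_args(argv[-1L])
  if (is.null(opts$out)) stop("--out DIR is required", call. = FALSE)
  int_or <- function(v, d) if (is.null(v)) d else as.integer(v)
  config <- run_config(
    out_dir = opts$out,
    preset = opts$preset %||% "default",
    n_participants = if (!is.null(opts$participants)) as.integer(opts$participants),
    n_days = if (!is.null(opts$days)) as.integer(opts$days),
    seed = int_or(opts$seed, 1L),
    horizon = int_or(opts$horizon, 3L),
    K = int_or(opts$k, 10L),
    algorithms = if (!is.null(opts$algorithms)) {
      strsplit(opts$algorithms, ",")[[1L]]
    } else c("logistic_regression", "rbf_svm", "gradient_boosted_trees",
             "mlp", "decision_tree", "random_forest"),
    n_trials = int_or(opts$trials, 90L),
    max_layers = int_or(opts$max_layers, 5L))
  run_pipeline(config, stages = stage)
  invisible(0L)
}
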