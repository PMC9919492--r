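# Random search over MLP hidden-layer architectures. Every trial samples a
# depth and per-layer widths uniformly, evaluates the candidate with the
# identical precomputed fold splits, and is ranked by mean cross-validated
# accuracy (MCC is recorded but never optimized).

#' Define an architecture search space
#'
#' @param max_layers maximum number of hidden layers (default 5).
#' @param width_choices candidate layer widths (default 4, 8, ..., 256).
#' @param n_trials number of random candidates to draw (default 90).
#' @param seed master seed; trial `t` derives its own seed via
#'   [child_seed()]`(seed, t)`.
#' @return a `search_space`.
#' @export
search_space <- function(max_layers = 5L, width_choices = c(4L, 8L, 16L, 32L, 64L, 128L, 256L),
                         n_trials = 90L, seed = 1L) {
  if (n_trials < 1L) config_error("n_trials must be >= 1")
  if (length(width_choices) < 1L || any(width_choices < 1L)) {
    config_error("width_choices must be non-empty positive integers")
  }
  if (max_layers < 1L) config_error("max_layers must be >= 1")
  structure(list(max_layers = as.integer(max_layers),
                 width_choices = as.integer(width_choices),
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "search_space")
}

#' Sample one architecture from a search space
#'
#' Layer count uniform on `1..max_layers`; each width uniform (with
#' replacement) on `width_choices`. Deterministic given the RNG state.
#'
#' @param space a [search_space()].
#' @return an [architecture_spec()].
#' @export
sample_architecture <- function(space) {
  stopifnot(inherits(space, "search_space"))
  n_layers <- sample.int(space$max_layers, 1L)
  widths <- space$width_choices[sample.int(length(space$width_choices),
                                           n_layers, replace = TRUE)]
  architecture_spec(widths)
}

#' Random search for the best MLP architectures
#'
#' Runs `space$n_trials` candidates, each evaluated with [run_kfold()] on
#' the same `folds`, ranks by mean accuracy (ties: higher mean MCC, then
#' lower trial index) and returns the `top_k`.
#'
#' @param instances a balanced `instance_set`.
#' @param folds a `fold_splits` shared by every trial.
#' @param space a [search_space()].
#' @param top_k how many best trials to retain (default 3).
#' @param hyperparams MLP fit hyperparameters forwarded to
#'   [classifier_spec()] (epochs, batch size, learning rate, patience).
#' @return an `arch_search`: `trials` (one row per trial: architecture,
#'   mean/sd accuracy and MCC, wall clock, best-so-far accuracy), `results`
#'   (per-trial `kfold_result`s), and `top` (indices of the `top_k` trials,
#'   best first).
#' @export
random_search <- function(instances, folds, space, top_k = 3L,
                          hyperparams = list()) {
  stopifnot(inherits(space, "search_space"))
  if (space$n_trials < 1L) config_error("n_trials must be >= 1")
  results <- vector("list", space$n_trials)
  rows <- vector("list", space$n_trials)
  for (t in seq_len(space$n_trials)) {
    trial_seed <- child_seed(space$seed, t)
    arch <- with_seed(trial_seed, sample_architecture(space))
    spec <- classifier_spec("mlp", hyperparams = hyperparams,
                            architecture = arch, seed = trial_seed)
    res <- run_kfold(instances, folds, spec)
    results[[t]] <- res
    s <- res$summary
    rows[[t]] <- data.frame(
      trial = t,
      architecture = paste(arch$hidden_layers, collapse = "-"),
      n_layers = length(arch$hidden_layers),
      accuracy_mean = s$mean[s$metric == "accuracy"],
      accuracy_sd = s$sd[s$metric == "accuracy"],
      mcc_mean = s$mean[s$metric == "mcc"],
      mcc_sd = s$sd[s$metric == "mcc"],
      wall_clock_s = sum(res$fit_seconds)
    )
  }
  trials <- do.call(rbind, rows)
  trials$best_so_far <- cummax(trials$accuracy_mean)
  rank_order <- order(-trials$accuracy_mean, -trials$mcc_mean, trials$trial)
  structure(list(trials = trials, results = results,
                 top = rank_order[seq_len(min(top_k, nrow(trials)))],
                 space = space),
            class = "arch_search")
}
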