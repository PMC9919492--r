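# Uniform classifier contract over six families. Five delegate to
# established implementations (glmnet, e1071, xgboost, rpart, ranger); the
# multilayer perceptron is implemented in-package (see mlp.R) because no
# installed backend trains networks with more than one hidden layer. A
# majority-vote baseline is included for chance-level comparisons.

CLASSIFIER_KINDS <- c("logistic_regression", "rbf_svm", "gradient_boosted_trees",
                      "mlp", "decision_tree", "random_forest", "majority_vote")

#' MLP hidden-layer architecture
#'
#' @param hidden_layers integer vector of hidden-layer widths, input side
#'   first; at least one layer, all widths positive.
#' @param activation hidden-layer nonlinearity (`"relu"` or `"tanh"`); the
#'   output is always a single sigmoid unit.
#' @return an `architecture_spec`.
#' @export
architecture_spec <- function(hidden_layers, activation = "relu") {
  hidden_layers <- as.integer(hidden_layers)
  if (length(hidden_layers) < 1L || any(hidden_layers < 1L)) {
    config_error("hidden_layers must contain at least one positive width")
  }
  if (!activation %in% c("relu", "tanh")) config_error("unsupported activation")
  structure(list(hidden_layers = hidden_layers, activation = activation),
            class = "architecture_spec")
}

#' Specify a classifier
#'
#' @param kind one of `r paste0('"', CLASSIFIER_KINDS, '"', collapse = ", ")`.
#' @param hyperparams named list of backend hyperparameters; anything not
#'   given falls through to the backend's defaults, which are snapshotted
#'   into the fit report.
#' @param architecture an [architecture_spec()]; required iff `kind = "mlp"`.
#' @param seed integer; all randomness in the fit is derived from it.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(kind, hyperparams = list(), architecture = NULL,
                            seed = 1L) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% CLASSIFIER_KINDS) {
    config_error("unknown classifier kind: ", paste(kind, collapse = ", "))
  }
  if (!is.list(hyperparams) ||
      (length(hyperparams) > 0L && is.null(names(hyperparams)))) {
    config_error("hyperparams must be a named list")
  }
  if (kind == "mlp" && !inherits(architecture, "architecture_spec")) {
    config_error("kind 'mlp' requires an architecture_spec")
  }
  if (kind != "mlp" && !is.null(architecture)) {
    config_error("architecture is only meaningful for kind 'mlp'")
  }
  structure(list(kind = kind, hyperparams = hyperparams,
                 architecture = architecture, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Build an unfitted classifier from a spec
#'
#' @param spec a [classifier_spec()].
#' @return a `stepcast_classifier` exposing the uniform contract
#'   [fit_with_tuning()] / [predict_labels()].
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  structure(list(spec = spec, fit = NULL, report = NULL),
            class = c(paste0("stepcast_", spec$kind), "stepcast_classifier"))
}

# densify and give canonical column names (ranger and rpart require them)
as_dense <- function(x) {
  m <- if (is.matrix(x)) x else as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

#' Fit a classifier, with the tune part steering early stopping
#'
#' The MLP uses `(tune_x, tune_y)` for early stopping; the other kinds fit
#' on the train part only and record that the tune part was unused. The
#' wall clock is measured around the fit call only.
#'
#' @param classifier an unfitted classifier from [build_classifier()].
#' @param x,y training features (matrix or `dgCMatrix`) and 0/1 labels.
#' @param tune_x,tune_y tuning part (may be `NULL` for non-MLP kinds).
#' @return the fitted classifier, with a `report` list: `kind`, `seconds`
#'   (fit wall-clock), `tune_used`, `backend`, and backend-specific details.
#' @export
fit_with_tuning <- function(classifier, x, y, tune_x = NULL, tune_y = NULL) {
  stopifnot(inherits(classifier, "stepcast_classifier"))
  if (is.null(x) || nrow(x) == 0L) config_error("empty training set")
  spec <- classifier$spec
  hp <- spec$hyperparams
  t0 <- proc.time()[["elapsed"]]
  fit <- with_seed(spec$seed, switch(
    spec$kind,
    logistic_regression = {
      # lightly ridge-penalized at a fixed small lambda: plain IRLS logistic
      # is impractical at 2,594 predictors, and the short warm-start path
      # keeps coordinate descent fast on the sparse one-hot design
      lam <- hp$lambda %||% 1e-3
      list(model = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                                  lambda = sort(unique(c(lam, 1e-1, 1e-2)),
                                                decreasing = TRUE),
                                  thresh = hp$thresh %||% 1e-6,
                                  standardize = FALSE),
           lambda = lam, backend = "glmnet")
    },
    rbf_svm = {
      list(model = e1071::svm(as_dense(x), factor(y, levels = 0:1),
                              kernel = "radial",
                              cost = hp$cost %||% 1,
                              gamma = hp$gamma %||% (1 / ncol(x)),
                              scale = FALSE),
           backend = "e1071")
    },
    gradient_boosted_trees = {
      params <- utils::modifyList(
        list(objective = "binary:logistic", nthread = 1L,
             max_depth = 6L, eta = 0.3, seed = spec$seed),
        hp[setdiff(names(hp), "nrounds")])
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      list(model = xgboost::xgb.train(params, dtrain,
                                      nrounds = hp$nrounds %||% 100L,
                                      verbose = 0),
           backend = "xgboost", params = params)
    },
    mlp = {
      list(model = mlp_fit(as_dense(x), y,
                           hidden = spec$architecture$hidden_layers,
                           activation = spec$architecture$activation,
                           epochs = hp$epochs %||% 40L,
                           batch_size = hp$batch_size %||% 64L,
                           lr = hp$lr %||% 1e-3,
                           patience = hp$patience %||% 5L,
                           tune_x = if (!is.null(tune_x)) as_dense(tune_x),
                           tune_y = tune_y,
                           seed = spec$seed),
           backend = "stepcast-mlp")
    },
    decision_tree = {
      df <- as.data.frame(as_dense(x))
      names(df) <- paste0("f", seq_len(ncol(x)))
      df$.y <- factor(y, levels = 0:1)
      ctrl <- rpart::rpart.control(
        maxdepth = hp$maxdepth %||% 30L,
        cp = hp$cp %||% 0.01,
        minsplit = hp$minsplit %||% 20L)
      list(model = rpart::rpart(.y ~ ., df, method = "class", control = ctrl),
           backend = "rpart")
    },
    random_forest = {
      list(model = ranger::ranger(x = as_dense(x), y = factor(y, levels = 0:1),
                                  num.trees = hp$num_trees %||% 500L,
                                  probability = TRUE,
                                  seed = spec$seed, num.threads = 1L),
           backend = "ranger")
    },
    majority_vote = {
      list(model = list(vote = as.integer(mean(y) >= 0.5)), backend = "stepcast")
    }
  ))
  seconds <- proc.time()[["elapsed"]] - t0
  classifier$fit <- fit
  classifier$report <- list(
    kind = spec$kind,
    seconds = seconds,
    tune_used = spec$kind == "mlp" && !is.null(tune_x),
    tune_n = if (is.null(tune_y)) 0L else length(tune_y),
    backend = fit$backend,
    backend_version = tryCatch(
      as.character(utils::packageVersion(fit$backend)), error = function(e) NA_character_),
    hyperparams = spec$hyperparams,
    details = if (spec$kind == "mlp") {
      fit$model[c("epochs_run", "best_epoch")]
    } else NULL
  )
  classifier
}

#' Predicted probabilities of the positive ("walked") class
#'
#' @param classifier a fitted classifier.
#' @param x feature matrix.
#' @return numeric vector of probabilities (or scores mapped to `[0, 1]`).
#' @export
predict_prob <- function(classifier, x) {
  stopifnot(inherits(classifier, "stepcast_classifier"), !is.null(classifier$fit))
  fit <- classifier$fit
  switch(classifier$spec$kind,
    logistic_regression = as.numeric(
      stats::predict(fit$model, x, s = fit$lambda, type = "response")),
    rbf_svm = {
      dv <- attr(stats::predict(fit$model, as_dense(x), decision.values = TRUE),
                 "decision.values")
      # libsvm's signed margin is positive for the class named first in the
      # column label ("a/b"); orient so positive means class 1, then squash
      first <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
      stats::plogis(if (identical(first, "1")) as.numeric(dv) else -as.numeric(dv))
    },
    gradient_boosted_trees = as.numeric(
      stats::predict(fit$model, xgboost::xgb.DMatrix(x))),
    mlp = as.numeric(mlp_predict(fit$model, as_dense(x))),
    decision_tree = {
      df <- as.data.frame(as_dense(x))
      names(df) <- paste0("f", seq_len(ncol(x)))
      as.numeric(stats::predict(fit$model, df, type = "prob")[, "1"])
    },
    random_forest = as.numeric(stats::predict(
      fit$model, data = as_dense(x), num.threads = 1L)$predictions[, "1"]),
    majority_vote = rep(as.numeric(fit$model$vote), nrow(x))
  )
}

#' Predicted binary labels (probability/score threshold 0.5)
#'
#' @inheritParams predict_prob
#' @return integer vector of 0/1 labels.
#' @export
predict_labels <- function(classifier, x) {
  as.integer(predict_prob(classifier, x) >= 0.5)
}
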