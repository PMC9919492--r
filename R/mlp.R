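# Minimal feed-forward network for binary classification: dense layers with
# ReLU (or tanh) activations, a single sigmoid output unit, binary
# cross-entropy loss, Adam updates on shuffled minibatches, and early
# stopping on the tune part. Written in-package because no installed R
# backend trains networks with more than one hidden layer; all heavy work is
# BLAS-bound matrix products.

mlp_init <- function(n_in, hidden, activation) {
  sizes <- c(n_in, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    sc <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sc), fan_in, sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, x, activation) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% par$W[[l]], 2L, par$b[[l]], `+`)
    acts[[l + 1L]] <- if (l == L) {
      stats::plogis(z)
    } else if (activation == "relu") {
      pmax(z, 0)
    } else {
      tanh(z)
    }
  }
  acts
}

mlp_bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Fit the in-package multilayer perceptron
#'
#' @param x dense numeric matrix (instances x features).
#' @param y 0/1 labels.
#' @param hidden integer vector of hidden-layer widths.
#' @param activation `"relu"` or `"tanh"`.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience epochs without tune-loss improvement tolerated before
#'   stopping (0 stops at the first non-improving epoch); ignored when no
#'   tune part is given.
#' @param tune_x,tune_y early-stopping part (optional).
#' @param seed RNG seed for initialization and minibatch shuffling.
#' @return an `stepcast_mlp` model list (weights, config, `epochs_run`,
#'   `best_epoch`).
#' @keywords internal
mlp_fit <- function(x, y, hidden, activation = "relu", epochs = 40L,
                    batch_size = 64L, lr = 1e-3, patience = 5L,
                    tune_x = NULL, tune_y = NULL, seed = 1L) {
  stopifnot(nrow(x) == length(y))
  y <- as.numeric(y)
  with_seed(seed, {
    par <- mlp_init(ncol(x), hidden, activation)
    L <- length(par$W)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(bb) bb * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
    best <- list(loss = Inf, par = par, epoch = 0L)
    stale <- 0L
    epochs_run <- 0L
    for (epoch in seq_len(epochs)) {
      epochs_run <- epoch
      ord <- sample.int(nrow(x))
      for (start in seq(1L, nrow(x), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, nrow(x))]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        acts <- mlp_forward(par, xb, activation)
        delta <- (acts[[L + 1L]] - yb) / length(idx)   # d(BCE)/d(z_out)
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            back <- delta %*% t(par$W[[l]])
            a <- acts[[l]]
            delta <- if (activation == "relu") back * (a > 0) else back * (1 - a^2)
          }
          t_step <- t_step + 1L
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
          par$W[[l]] <- par$W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          par$b[[l]] <- par$b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      if (!is.null(tune_x) && length(tune_y) > 0L) {
        p_tune <- mlp_forward(par, tune_x, activation)[[L + 1L]]
        loss <- mlp_bce(as.numeric(p_tune), as.numeric(tune_y))
        if (loss < best$loss - 1e-9) {
          best <- list(loss = loss, par = par, epoch = epoch)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale > patience) break
        }
      }
    }
    final <- if (is.finite(best$loss)) best$par else par
    structure(list(par = final, activation = activation, hidden = hidden,
                   epochs_run = epochs_run,
                   best_epoch = if (is.finite(best$loss)) best$epoch else epochs_run),
              class = "stepcast_mlp")
  })
}

#' @rdname mlp_fit
#' @param model a fitted `stepcast_mlp`.
#' @keywords internal
mlp_predict <- function(model, x) {
  acts <- mlp_forward(model$par, x, model$activation)
  as.numeric(acts[[length(acts)]])
}
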