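#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a master seed and a stream index
#'
#' Every stochastic stage of the pipeline draws its randomness from a child
#' seed derived deterministically from one master seed, so that (a) a whole
#' run is reproducible from a single integer and (b) per-participant streams
#' are stable under changes to cohort size or simulation order.
#'
#' @param seed master seed (integer).
#' @param index non-negative stream index.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index), length(index) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; Lehmer-style mixing
  s <- (abs(seed) %% m) + 1
  for (k in c(index + 1, 16807)) s <- (s * 48271 + k) %% m
  as.integer(s %% (m - 1L)) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent condition class so callers/tests can distinguish
# configuration errors from runtime errors.
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("stepcast_config_error", "error")))
}
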