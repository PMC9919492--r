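# Class balancing and the K-fold train/tune/test harness. Balancing happens
# once, globally, before the single shuffle that defines the folds; every
# classifier and every architecture trial then sees identical splits.

#' Balance classes by undersampling the majority class
#'
#' All minority-class instances are kept; the majority class is sampled
#' uniformly without replacement down to the minority count.
#'
#' @param instances an `instance_set` with both classes present.
#' @param seed integer seed for the majority-class draw.
#' @return a balanced `instance_set` (equal class counts), rows in original
#'   order.
#' @export
undersample_balance <- function(instances, seed) {
  stopifnot(inherits(instances, "instance_set"))
  pos <- which(instances$label == 1L)
  neg <- which(instances$label == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    config_error("both classes must be non-empty to balance")
  }
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  kept_major <- with_seed(seed, sort(sample(majority, length(minority))))
  keep <- sort(c(minority, kept_major))
  out <- subset_instances(instances, keep)
  out$provenance$balance <- list(seed = as.integer(seed),
                                 n_minority = length(minority),
                                 n_majority_before = length(majority))
  out
}

#' Shuffle and split into K train/tune/test folds
#'
#' One seeded shuffle assigns every instance to one of `K` near-equal parts
#' (sizes differ by at most 1). Fold `i` uses part `i` as its test set, the
#' cyclic successor part as its tune set, and the remaining `K - 2` parts for
#' training; across folds every instance appears in exactly one test set.
#'
#' @param n number of instances, or an `instance_set`.
#' @param K number of folds (default 10, minimum 3 so that train, tune and
#'   test are disjoint).
#' @param seed integer seed for the shuffle.
#' @return a `fold_splits` object: list of `K` folds, each
#'   `list(fold_index, train_ids, tune_ids, test_ids)`, with the seed and
#'   part assignment attached.
#' @export
shuffle_and_fold <- function(n, K = 10L, seed = 1L) {
  if (inherits(n, "instance_set")) n <- nrow(n$features)
  n <- as.integer(n); K <- as.integer(K)
  if (K < 3L) config_error("K must be >= 3 so that train, tune and test parts are disjoint")
  if (n < K) config_error("need at least K instances to form K folds")
  perm <- with_seed(seed, sample.int(n))
  # part sizes differ by at most one; first (n mod K) parts get the extra
  part_of <- integer(n)
  sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  part_of[perm] <- rep.int(seq_len(K), sizes)
  folds <- lapply(seq_len(K), function(i) {
    tune_part <- (i %% K) + 1L
    list(fold_index = i,
         train_ids = which(!part_of %in% c(i, tune_part)),
         tune_ids = which(part_of == tune_part),
         test_ids = which(part_of == i))
  })
  structure(folds, seed = as.integer(seed), K = K, n = n, part_of = part_of,
            class = "fold_splits")
}

#' Write/read a fold manifest for exact replay
#' @param folds a `fold_splits`.
#' @param path JSON file path.
#' @return `path`, invisibly (writer); a `fold_splits` (reader).
#' @export
write_fold_manifest <- function(folds, path) {
  stopifnot(inherits(folds, "fold_splits"))
  jsonlite::write_json(
    list(seed = attr(folds, "seed"), K = attr(folds, "K"), n = attr(folds, "n"),
         part_of = attr(folds, "part_of")),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_manifest
#' @export
read_fold_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  part_of <- as.integer(m$part_of)
  K <- as.integer(m$K)
  folds <- lapply(seq_len(K), function(i) {
    tune_part <- (i %% K) + 1L
    list(fold_index = i,
         train_ids = which(!part_of %in% c(i, tune_part)),
         tune_ids = which(part_of == tune_part),
         test_ids = which(part_of == i))
  })
  structure(folds, seed = as.integer(m$seed), K = K, n = as.integer(m$n),
            part_of = part_of, class = "fold_splits")
}
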