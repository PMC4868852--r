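# Internal helpers: argument checking, seed streams, stratified folds.

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input("'%s' must be a numeric matrix", name)
  if (!all(is.finite(x)))
    stop_input("'%s' contains non-finite values", name)
  invisible(x)
}

#' Derive a child RNG seed from a base seed and a stream counter
#'
#' All randomness in the package flows from one user seed; independent stages
#' and subjects draw from child streams derived by counter so that results do
#' not depend on evaluation order.  Seeds stay below 2^31.
#'
#' @param seed integer base seed.
#' @param stream non-negative integer stream counter.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 7919 + 11) %%
               2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified k-fold assignment
#'
#' Assigns each subject to exactly one test fold, keeping class proportions as
#' balanced as integer arithmetic allows.  Assignment depends only on the
#' labels and the seed, never on feature values.
#'
#' @param labels vector of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2) stop_input("k must be at least 2")
  tab <- table(labels)
  if (any(tab < k))
    stop_input("stratification impossible: class '%s' has %d subjects for %d folds",
               names(tab)[which.min(tab)], min(tab), k)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}
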