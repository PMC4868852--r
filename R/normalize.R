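#' Normalization configuration
#'
#' @param scheme one or more of `"none"`, `"l1"`, `"l2"`, `"sqrt"` (power),
#'   `"L2A"`, `"L2AL2W"`; when several are given they are applied in order by
#'   the pipeline.
#' @param rho power-normalization exponent in `[0, 1]` (0.5 by default, the
#'   signed square root).
#' @return an object of class `nf_norm_config`.
#' @export
normalization_config <- function(scheme = c("sqrt", "L2AL2W"), rho = 0.5) {
  known <- c("none", "l1", "l2", "sqrt", "L2A", "L2AL2W")
  if (!all(scheme %in% known))
    stop_input("unknown normalization scheme(s): %s",
               paste(setdiff(scheme, known), collapse = ", "))
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1)
    stop_input("rho must be a single value in [0, 1]")
  structure(list(scheme = scheme, rho = rho), class = "nf_norm_config")
}

#' Normalize a single feature vector
#'
#' Power (signed-root) normalization `x <- sign(x) |x|^rho` suppresses
#' dominant components before classification; `l1`/`l2` rescale to unit norm
#' (the zero vector is returned unchanged).
#'
#' @param v numeric vector with finite entries.
#' @param scheme `"none"`, `"sqrt"`, `"l1"` or `"l2"`.
#' @param rho power exponent for `"sqrt"`.
#' @return the normalized vector.
#' @export
vector_normalize <- function(v, scheme = c("sqrt", "l1", "l2", "none"),
                             rho = 0.5) {
  scheme <- match.arg(scheme)
  if (!is.numeric(v) || !all(is.finite(v)))
    stop_input("input vector must be finite")
  switch(scheme,
         none = v,
         sqrt = sign(v) * abs(v)^rho,
         l1 = { s <- sum(abs(v)); if (s > 0) v / s else v },
         l2 = { s <- sqrt(sum(v^2)); if (s > 0) v / s else v })
}

#' Inter- and intra-subject (L2AL2W) cohort normalization
#'
#' Two-step scheme for a cohort feature matrix with one subject per row:
#' step A (across subjects) divides every feature dimension by its l2 norm
#' over the *training* subjects, and applies the same divisors to the test
#' rows, so no test statistics leak into training; step W (within subject)
#' scales every subject row to unit l2 norm.  Zero-norm dimensions and zero
#' rows are left unscaled.
#'
#' @param train `n x p` training matrix (subjects in rows).
#' @param test optional `m x p` matrix normalized with the training divisors.
#' @return list with `train`, `test` (or NULL) and the per-dimension
#'   `col_norms` used in step A.
#' @export
normalize_cohort_l2al2w <- function(train, test = NULL) {
  check_finite_matrix(train, "train")
  if (!is.null(test)) {
    check_finite_matrix(test, "test")
    if (ncol(test) != ncol(train))
      stop_input("train and test have different feature dimensions (%d vs %d)",
                 ncol(train), ncol(test))
  }
  col_norms <- sqrt(colSums(train^2))
  div <- ifelse(col_norms > 0, col_norms, 1)
  step_w <- function(m) {
    rn <- sqrt(rowSums(m^2))
    nz <- rn > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rn[nz]
    m
  }
  out_train <- step_w(sweep(train, 2, div, `/`))
  out_test <- if (is.null(test)) NULL else step_w(sweep(test, 2, div, `/`))
  list(train = out_train, test = out_test, col_norms = col_norms)
}
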