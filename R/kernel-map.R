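# Explicit feature maps for additive homogeneous kernels, so that a linear
# SVM reproduces the chi-square, Jensen-Shannon or Hellinger kernel.  The
# chi2/JS maps are the finite sampled approximation of the kernel's spectral
# representation: for a 1-homogeneous kernel k(x,y) = sqrt(xy) K(log y - log x)
# with spectrum kappa(omega), sampling the spectrum at frequencies j*L,
# j = -n..n, yields a (2n+1)-dimensional map per input component whose inner
# products approximate k.  Larger n reduces the truncation error; smaller L
# widens the period over which the approximation holds.

kernel_spectrum <- function(kind, w) {
  switch(kind,
         kchi2 = 1 / cosh(pi * w),
         kjs = (2 / log(4)) / cosh(pi * w) / (1 + 4 * w^2))
}

#' Closed-form additive kernels (used as oracles and for reference)
#'
#' `kchi2(x, y) = sum_i 2 x_i y_i / (x_i + y_i)`;
#' `kjs(x, y) = sum_i (x_i/2) log2((x_i+y_i)/x_i) + (y_i/2) log2((x_i+y_i)/y_i)`
#' with `0 * log` terms defined as 0.
#'
#' @param kind `"kchi2"` or `"kjs"`.
#' @param x,y nonnegative numeric vectors of equal length.
#' @return the kernel value.
#' @export
additive_kernel <- function(kind = c("kchi2", "kjs"), x, y) {
  kind <- match.arg(kind)
  if (any(x < 0) || any(y < 0)) stop_input("additive kernels require nonnegative input")
  s <- x + y
  if (kind == "kchi2") {
    sum(ifelse(s > 0, 2 * x * y / ifelse(s > 0, s, 1), 0))
  } else {
    t1 <- ifelse(x > 0, x / 2 * log2(s / ifelse(x > 0, x, 1)), 0)
    t2 <- ifelse(y > 0, y / 2 * log2(s / ifelse(y > 0, y, 1)), 0)
    sum(t1 + t2)
  }
}

#' Kernel feature-map configuration
#'
#' @param kind `"linear"` (identity), `"hellinger"` (element-wise signed
#'   square root, exact), `"kchi2"` or `"kjs"` (sampled approximate maps).
#' @param order_n samples per side for the approximate maps (output length
#'   becomes `input length * (2 * order_n + 1)`).
#' @param period sampling period `L`; `NULL` selects `0.65 / sqrt(order_n)`,
#'   which balances spectrum truncation against periodization so the
#'   approximation error decreases with `order_n`.
#' @return an object of class `nf_kernel_map`.
#' @export
kernel_map_config <- function(kind = c("linear", "hellinger", "kchi2", "kjs"),
                              order_n = 3, period = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("kchi2", "kjs")) {
    if (order_n < 1) stop_input("order_n must be >= 1 for %s", kind)
    if (is.null(period)) period <- 0.65 / sqrt(order_n)
    if (period <= 0) stop_input("period must be > 0")
  }
  structure(list(kind = kind, order_n = as.integer(order_n), period = period),
            class = "nf_kernel_map")
}

#' Apply an explicit kernel feature map to a vector
#'
#' `linear` returns the input; `hellinger` the element-wise signed square
#' root (so inner products of mapped nonnegative vectors equal
#' `sum sqrt(x_i y_i)` exactly); `kchi2`/`kjs` the sampled approximate map of
#' the corresponding additive kernel, requiring nonnegative input.  Zero
#' components map to zero blocks.
#'
#' @param v numeric vector (nonnegative for `kchi2`/`kjs`).
#' @param cfg a [kernel_map_config()].
#' @return the mapped vector: same length for `linear`/`hellinger`,
#'   `length(v) * (2 * order_n + 1)` for the approximate maps, with the
#'   `2n+1` map coordinates of component `i` stored contiguously.
#' @export
apply_kernel_map <- function(v, cfg = kernel_map_config()) {
  stopifnot(inherits(cfg, "nf_kernel_map"))
  if (!is.numeric(v) || !all(is.finite(v))) stop_input("input vector must be finite")
  if (cfg$kind == "linear") return(v)
  if (cfg$kind == "hellinger") return(sign(v) * sqrt(abs(v)))
  bad <- which(v < 0)
  if (length(bad) > 0)
    stop_input("%s kernel map requires nonnegative input; first negative entry at index %d",
               cfg$kind, bad[1])
  n <- cfg$order_n; L <- cfg$period
  out <- matrix(0, 2 * n + 1, length(v))
  pos <- v > 0
  if (any(pos)) {
    xl <- log(v[pos])
    out[1, pos] <- sqrt(v[pos] * L * kernel_spectrum(cfg$kind, 0))
    for (j in seq_len(n)) {
      r <- sqrt(2 * v[pos] * L * kernel_spectrum(cfg$kind, j * L))
      out[2 * j, pos] <- r * cos(j * L * xl)
      out[2 * j + 1, pos] <- r * sin(j * L * xl)
    }
  }
  as.vector(out)
}
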