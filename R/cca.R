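#' Fit two-view canonical correlation analysis
#'
#' Finds paired projection bases `B1`, `B2` maximizing the correlation of the
#' two views in a common space, with the view covariances shrunk by
#' `epsilon * I` (`Sigma_11 + eps I`, `Sigma_22 + eps I`) so the problem is
#' well posed when features outnumber subjects.  The generalized
#' eigendecomposition is solved directly for `d <= n`, and in the span of the
#' centered data (via thin SVD) for `d > n`, which keeps the cost `O(n^3)`
#' for the wide matrices produced by encoded image features.
#'
#' @param X1,X2 `d x n` matrices, one subject per column.
#' @param c number of components to keep; default `min(d, n-1)` truncated to
#'   components with correlation >= 0.01.
#' @param epsilon covariance shrinkage; `NULL` (default) uses
#'   `1e-3 * mean diagonal of the pooled covariance`; `0` requests the
#'   unregularized problem and fails on singular covariances.
#' @return an object of class `nf_cca` with bases `B1`, `B2` (columns
#'   normalized so `B'(Sigma + eps I)B = I`, ordered by descending
#'   correlation), `correlations`, `epsilon`, and the training means.
#' @export
fit_cca <- function(X1, X2, c = NULL, epsilon = NULL) {
  check_finite_matrix(X1, "X1"); check_finite_matrix(X2, "X2")
  if (!all(dim(X1) == dim(X2)))
    stop_input("X1 (%dx%d) and X2 (%dx%d) must have the same shape",
               nrow(X1), ncol(X1), nrow(X2), ncol(X2))
  d <- nrow(X1); n <- ncol(X1)
  if (n < 3) stop_input("need at least 3 subjects to fit CCA, got %d", n)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  X1c <- X1 - m1; X2c <- X2 - m2
  if (is.null(epsilon)) {
    pooled_diag <- (rowSums(X1c^2) + rowSums(X2c^2)) / (2 * (n - 1))
    epsilon <- 1e-3 * mean(pooled_diag)
  }
  if (epsilon < 0) stop_input("epsilon must be >= 0")
  cmax <- min(d, n - 1)

  if (d <= n) {
    S11 <- tcrossprod(X1c) / (n - 1) + diag(epsilon, d)
    S22 <- tcrossprod(X2c) / (n - 1) + diag(epsilon, d)
    S12 <- tcrossprod(X1c, X2c) / (n - 1)
    sol <- tryCatch({
      A <- solve(S11, S12 %*% solve(S22, t(S12)))
      eig <- eigen(A)
      list(vec = Re(eig$vectors), val = Re(eig$values))
    }, error = function(e)
      stop_input("regularized covariance is singular (%s); refit with epsilon > 0",
                 conditionMessage(e)))
    ord <- order(sol$val, decreasing = TRUE)[seq_len(cmax)]
    A1 <- sol$vec[, ord, drop = FALSE]
    # normalize so B1' S11r B1 = I
    sc <- sqrt(colSums(A1 * (S11 %*% A1)))
    B1 <- sweep(A1, 2, sc, `/`)
    B2 <- solve(S22, t(S12) %*% B1)
    sc2 <- sqrt(colSums(B2 * (S22 %*% B2)))
    sc2[sc2 == 0] <- 1
    B2 <- sweep(B2, 2, sc2, `/`)
    rho <- colSums(B1 * (S12 %*% B2))
    flip <- rho < 0
    B2[, flip] <- -B2[, flip, drop = FALSE]
    rho <- abs(rho)
  } else {
    sv1 <- svd(X1c); sv2 <- svd(X2c)
    keep1 <- sv1$d > max(d, n) * .Machine$double.eps * sv1$d[1]
    keep2 <- sv2$d > max(d, n) * .Machine$double.eps * sv2$d[1]
    U1 <- sv1$u[, keep1, drop = FALSE]; d1 <- sv1$d[keep1]
    U2 <- sv2$u[, keep2, drop = FALSE]; d2 <- sv2$d[keep2]
    V1 <- sv1$v[, keep1, drop = FALSE]; V2 <- sv2$v[, keep2, drop = FALSE]
    if (epsilon == 0 && (length(d1) < min(d, n - 1) || length(d2) < min(d, n - 1)))
      stop_input("rank-deficient covariance with epsilon = 0; refit with epsilon > 0")
    G <- (d1 * crossprod(V1, V2)) %*% diag(d2, length(d2)) / (n - 1)
    lam1 <- d1^2 / (n - 1) + epsilon
    lam2 <- d2^2 / (n - 1) + epsilon
    M <- (G / lam1) %*% (t(G) / lam2)
    eig <- eigen(M)
    cmax <- min(cmax, length(d1))
    ord <- order(Re(eig$values), decreasing = TRUE)[seq_len(cmax)]
    a <- Re(eig$vectors)[, ord, drop = FALSE]
    sc <- sqrt(colSums(a^2 * lam1))
    a <- sweep(a, 2, sc, `/`)
    b <- (t(G) %*% a) / lam2
    sc2 <- sqrt(colSums(b^2 * lam2))
    sc2[sc2 == 0] <- 1
    b <- sweep(b, 2, sc2, `/`)
    rho <- colSums(a * (G %*% b))
    flip <- rho < 0
    b[, flip] <- -b[, flip, drop = FALSE]
    rho <- abs(rho)
    B1 <- U1 %*% a
    B2 <- U2 %*% b
  }

  rho <- pmin(pmax(rho, 0), 1 + 1e-8)
  if (is.null(c)) {
    c_use <- max(1L, sum(rho >= 0.01))
  } else {
    if (c < 1 || c > cmax)
      stop_input("c must be between 1 and min(d, n-1) = %d", cmax)
    c_use <- as.integer(c)
  }
  idx <- seq_len(c_use)
  structure(list(B1 = B1[, idx, drop = FALSE], B2 = B2[, idx, drop = FALSE],
                 correlations = rho[idx], epsilon = epsilon,
                 mean1 = m1, mean2 = m2, c = c_use, d = d, n_train = n),
            class = "nf_cca")
}

#' Project both views into the canonical space
#'
#' `Z = B' (X - training mean)` for each view.  On the training data the
#' per-component correlation of `Z1` and `Z2` reproduces the stored canonical
#' correlations (exactly for `epsilon = 0`).
#'
#' @param model a fitted [fit_cca()] model.
#' @param X1,X2 `d x m` matrices of the two views.
#' @return list with `Z1`, `Z2` (`c x m`).
#' @export
project_cca <- function(model, X1, X2) {
  stopifnot(inherits(model, "nf_cca"))
  if (nrow(X1) != model$d || nrow(X2) != model$d)
    stop_input("feature dimension %d does not match fitted dimension %d",
               nrow(X1), model$d)
  if (ncol(X1) != ncol(X2)) stop_input("X1 and X2 must have equal column counts")
  list(Z1 = crossprod(model$B1, X1 - model$mean1),
       Z2 = crossprod(model$B2, X2 - model$mean2))
}

#' Stack original and canonical features into the augmented representation
#'
#' Builds `F = [X1; X2; Z1; Z2]` by row-wise stacking, so each subject
#' carries both its modality-individual features and the shared canonical
#' projections.  No rescaling is applied.
#'
#' @param X1,X2 original per-modality features (`d x n`).
#' @param Z1,Z2 canonical projections (`c x n`).
#' @return an object of class `nf_augmented` with the stacked matrix `F` and
#'   a `blocks` list of row index ranges recovering each input block.
#' @export
augment_features <- function(X1, X2, Z1, Z2) {
  ns <- c(ncol(X1), ncol(X2), ncol(Z1), ncol(Z2))
  if (length(unique(ns)) != 1)
    stop_input("column counts disagree: %s", paste(ns, collapse = ", "))
  rows <- c(nrow(X1), nrow(X2), nrow(Z1), nrow(Z2))
  ends <- cumsum(rows)
  starts <- c(1, head(ends, -1) + 1)
  blocks <- Map(function(s, e) s:e, starts, ends)
  names(blocks) <- c("X1", "X2", "Z1", "Z2")
  structure(list(F = rbind(X1, X2, Z1, Z2), blocks = blocks),
            class = "nf_augmented")
}

#' Save / load a fitted CCA model
#'
#' Versioned serialization with an exact round trip of bases, correlations,
#' means and the regularizer.
#' @param model an `nf_cca`.
#' @param path file path.
#' @export
save_cca_model <- function(model, path) {
  stopifnot(inherits(model, "nf_cca"))
  saveRDS(c(list(format = "nf_cca", version = 1L), unclass(model)), path)
  invisible(path)
}

#' @rdname save_cca_model
#' @export
load_cca_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nf_cca")) stop_input("not a CCA model file: %s", path)
  obj$format <- NULL; obj$version <- NULL
  structure(obj, class = "nf_cca")
}
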