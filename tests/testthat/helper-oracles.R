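# Independent oracles used to freeze expected values.  These deliberately
# take different computational routes from the package implementation.

# CCA by whitening each view with the (regularized) inverse covariance
# square root and taking the SVD of the cross matrix.
oracle_cca <- function(X1, X2, epsilon = 0) {
  n <- ncol(X1)
  X1c <- X1 - rowMeans(X1); X2c <- X2 - rowMeans(X2)
  S11 <- tcrossprod(X1c) / (n - 1) + diag(epsilon, nrow(X1))
  S22 <- tcrossprod(X2c) / (n - 1) + diag(epsilon, nrow(X2))
  S12 <- tcrossprod(X1c, X2c) / (n - 1)
  inv_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  W1 <- inv_sqrt(S11); W2 <- inv_sqrt(S22)
  sv <- svd(W1 %*% S12 %*% W2)
  list(correlations = sv$d, B1 = W1 %*% sv$u, B2 = W2 %*% sv$v)
}

# brute-force dual QP for the soft-margin linear SVM on tiny instances:
# enumerate all active sets (each alpha at 0, at C, or free), solve the KKT
# system for the free variables, keep the feasible optimum
oracle_svm_objective <- function(X, y, C) {
  n <- ncol(X)
  Q <- (y %o% y) * crossprod(X)
  best <- -Inf
  states <- expand.grid(rep(list(0:2), n))
  for (s in seq_len(nrow(states))) {
    st <- as.integer(states[s, ])
    a <- ifelse(st == 2, C, 0)
    fr <- which(st == 1)
    if (length(fr) > 0) {
      A <- rbind(cbind(Q[fr, fr, drop = FALSE], y[fr]), c(y[fr], 0))
      rhs <- c(1 - (if (any(st == 2))
        Q[fr, st == 2, drop = FALSE] %*% rep(C, sum(st == 2)) else
          rep(0, length(fr))),
        -sum(C * y[st == 2]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a[fr] <- sol[seq_along(fr)]
      if (any(a[fr] < -1e-9 | a[fr] > C + 1e-9)) next
    } else if (abs(sum(a * y)) > 1e-9) next
    obj <- sum(a) - 0.5 * as.numeric(t(a) %*% Q %*% a)
    if (obj > best) best <- obj
  }
  best
}

svm_primal_objective <- function(model, X, y, C) {
  f <- svm_decision(model, X)
  0.5 * sum(model$w^2) + C * sum(pmax(0, 1 - y * f))
}

# direct-summation VLAD oracle
oracle_vlad <- function(X, cluster, centroids) {
  K <- nrow(centroids)
  out <- NULL
  for (k in seq_len(K)) {
    v <- rep(0, ncol(X))
    for (m in which(cluster == k)) v <- v + X[m, ] - centroids[k, ]
    out <- c(out, v)
  }
  out
}

# closed-form additive kernels (independent of the package helper)
oracle_chi2_kernel <- function(x, y) {
  s <- x + y
  sum(ifelse(s > 0, 2 * x * y / pmax(s, .Machine$double.xmin), 0))
}
oracle_js_kernel <- function(x, y) {
  s <- x + y
  t1 <- ifelse(x > 0, x / 2 * log2(s / pmax(x, .Machine$double.xmin)), 0)
  t2 <- ifelse(y > 0, y / 2 * log2(s / pmax(y, .Machine$double.xmin)), 0)
  sum(t1 + t2)
}

# brute-force per-pixel gradient orientation histogram of a whole slice
oracle_orientation_histogram <- function(I, nbins) {
  H <- nrow(I); W <- ncol(I)
  gx <- (I[, c(2:W, W)] - I[, c(1, 1:(W - 1))]) / 2
  gy <- (I[c(2:H, H), ] - I[c(1, 1:(H - 1)), ]) / 2
  hist <- rep(0, nbins)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    m <- sqrt(gx[r, cc]^2 + gy[r, cc]^2)
    if (m > 0) {
      a <- atan2(gy[r, cc], gx[r, cc]) %% (2 * pi)
      b <- min(floor(a / (2 * pi) * nbins), nbins - 1) + 1
      hist[b] <- hist[b] + m
    }
  }
  hist
}

# small cohort + feature-level CV used by several tests
quick_vector_cv <- function(X, y, k = 5, seed = 1, augmented = FALSE) {
  folds <- stratified_folds(y, k, seed)
  correct <- 0
  for (f in seq_len(k)) {
    tr <- folds != f
    if (augmented) {
      cm <- fit_cca(X$X1[, tr, drop = FALSE], X$X2[, tr, drop = FALSE])
      pr_tr <- project_cca(cm, X$X1[, tr, drop = FALSE], X$X2[, tr, drop = FALSE])
      pr_te <- project_cca(cm, X$X1[, !tr, drop = FALSE], X$X2[, !tr, drop = FALSE])
      Ftr <- rbind(X$X1[, tr, drop = FALSE], X$X2[, tr, drop = FALSE],
                   pr_tr$Z1, pr_tr$Z2)
      Fte <- rbind(X$X1[, !tr, drop = FALSE], X$X2[, !tr, drop = FALSE],
                   pr_te$Z1, pr_te$Z2)
    } else {
      Ftr <- X$X1[, tr, drop = FALSE]
      Fte <- X$X1[, !tr, drop = FALSE]
    }
    mdl <- train_linear_svm(Ftr, y[tr], C = 1)
    correct <- correct + sum(score_predict(svm_decision(mdl, Fte)) == y[!tr])
  }
  correct / length(y)
}

tiny_experiment_config <- function(seed = 5, ...) {
  experiment_config(
    data = list(cohort = cohort_spec(n_per_class = 6,
                                     volume_shape = c(24, 24, 24),
                                     shared_effect = 1, modality_noise = 0.2,
                                     seed = seed)),
    tasks = "AD_vs_NC",
    representations = c("MRI", "MRIPETHF"),
    K = list(bovw = 8, vlad = 4),
    cv = list(k = 3, repeats = 1),
    inner_k = 3,
    seed = seed, ...)
}
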