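#' Train a soft-margin linear SVM
#'
#' Thin wrapper around the libsvm solver (via e1071) with a fixed
#' orientation: decision values are positive for the `+1` class.  Features
#' are never rescaled internally.
#'
#' @param X `features x subjects` matrix.
#' @param y labels in `{-1, +1}`; both classes must be present.
#' @param C soft-margin cost (> 0).
#' @param tolerance solver termination tolerance.
#' @return an object of class `nf_svm` with the primal weight vector `w`,
#'   intercept `b` and the underlying model.
#' @export
train_linear_svm <- function(X, y, C = 1, tolerance = 1e-4) {
  check_finite_matrix(X, "X")
  if (!all(y %in% c(-1, 1))) stop_input("labels must be -1 or +1")
  if (length(unique(y)) < 2) stop_input("both classes must be present")
  if (length(y) != ncol(X)) stop_input("ncol(X) must equal length(y)")
  if (!is.numeric(C) || C <= 0) stop_input("cost C must be > 0")
  m <- e1071::svm(x = t(X), y = factor(y, levels = c(-1, 1)),
                  kernel = "linear", cost = C, scale = FALSE,
                  tolerance = tolerance)
  w <- as.vector(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # libsvm orients the decision value toward its first stored label
  first_label <- levels(factor(y, levels = c(-1, 1)))[m$labels[1]]
  if (first_label == "-1") { w <- -w; b <- -b }
  structure(list(w = w, b = b, C = C), class = "nf_svm")
}

#' Signed decision values of a linear SVM
#' @param model an `nf_svm`.
#' @param X `features x subjects` matrix.
#' @return numeric vector of decision values, positive toward class `+1`.
#' @export
svm_decision <- function(model, X) {
  stopifnot(inherits(model, "nf_svm"))
  if (nrow(X) != length(model$w))
    stop_input("feature dimension %d does not match model dimension %d",
               nrow(X), length(model$w))
  as.vector(crossprod(X, model$w)) + model$b
}

#' Bundle BoVW and VLAD decision scores with a fusion weight
#'
#' @param s_bovw,s_vlad decision-value vectors of the two classifiers.
#' @param alpha fusion weight in `[0, 1]`.
#' @return an object of class `nf_scores` with `s_fused =
#'   alpha * s_bovw + (1 - alpha) * s_vlad`.
#' @export
score_set <- function(s_bovw, s_vlad, alpha) {
  if (length(s_bovw) != length(s_vlad))
    stop_input("score vectors have different lengths (%d vs %d)",
               length(s_bovw), length(s_vlad))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop_input("alpha must be a single value in [0, 1]")
  structure(list(s_bovw = s_bovw, s_vlad = s_vlad, alpha = alpha,
                 s_fused = alpha * s_bovw + (1 - alpha) * s_vlad),
            class = "nf_scores")
}

#' Fused decision values of a score set
#' @param scores an [score_set()].
#' @return the element-wise convex combination of the two score vectors.
#' @export
fuse_scores <- function(scores) {
  stopifnot(inherits(scores, "nf_scores"))
  scores$s_fused
}

#' Class prediction from decision values
#'
#' Zero decision values map to the positive class (the documented tie rule).
#' @param s decision values.
#' @return predictions in `{-1, +1}`.
#' @export
score_predict <- function(s) ifelse(s >= 0, 1, -1)

#' Choose the score-fusion weight on inner-validation scores
#'
#' Returns the grid weight maximizing the accuracy of
#' `sign(alpha * s_bovw + (1 - alpha) * s_vlad)` on held-out inner scores.
#' Ties are broken toward 0.5, then toward the smaller weight.
#'
#' @param inner_scores_bovw,inner_scores_vlad inner-validation decision values.
#' @param inner_labels labels in `{-1, +1}`.
#' @param grid candidate weights in `[0, 1]`.
#' @return the selected weight.
#' @export
select_fusion_weight <- function(inner_scores_bovw, inner_scores_vlad,
                                 inner_labels, grid = seq(0, 1, by = 0.1)) {
  if (length(grid) == 0 || any(grid < 0 | grid > 1))
    stop_input("fusion grid must be a nonempty subset of [0, 1]")
  acc <- vapply(grid, function(a)
    mean(score_predict(a * inner_scores_bovw + (1 - a) * inner_scores_vlad)
         == inner_labels), numeric(1))
  best <- which(acc >= max(acc) - 1e-12)
  pick <- best[order(abs(grid[best] - 0.5), grid[best])][1]
  grid[pick]
}

# tie-averaged rank AUC (equivalent to the Mann-Whitney statistic)
auc_rank <- function(labels, scores) {
  np <- sum(labels == 1); nn <- sum(labels == -1)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Confusion-derived evaluation metrics and AUC for one fold
#'
#' Computes `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)`,
#' `SPEC = TN/(TN+FP)`, `BAC = (SEN+SPEC)/2`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)` and the tie-averaged rank AUC of the decision values.
#' Undefined ratios (zero denominators) are reported as `NA`, not 0.
#'
#' @param labels true labels in `{-1, +1}`.
#' @param predictions predicted labels in `{-1, +1}`.
#' @param decision_values decision values used for the AUC.
#' @return named numeric vector with ACC, SEN, SPEC, BAC, PPV, NPV, AUC.
#' @export
compute_metrics <- function(labels, predictions, decision_values) {
  if (length(labels) == 0) stop_input("empty input")
  if (length(predictions) != length(labels) ||
      length(decision_values) != length(labels))
    stop_input("labels, predictions and decision values must have equal length")
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == -1 & predictions == -1)
  fp <- sum(labels == -1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == -1)
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  sen <- ratio(tp, tp + fn); spec <- ratio(tn, tn + fp)
  c(ACC = (tp + tn) / length(labels), SEN = sen, SPEC = spec,
    BAC = mean(c(sen, spec)), PPV = ratio(tp, tp + fp),
    NPV = ratio(tn, tn + fn), AUC = auc_rank(labels, decision_values))
}

# --- Gram-domain linear SVM -------------------------------------------------
# The CV pipeline's representations have far more features than subjects, so
# the soft-margin linear SVM is solved through the subjects' Gram matrix:
# an explicit point set with the same Gram (eigen square root) yields the
# identical dual solution, and decision values for any subjects follow from
# cross inner products with the training set.

train_svm_gram <- function(G, y, C = 1, tolerance = 1e-4) {
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n)
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Xt <- sqrt(lam) * t(e$vectors)   # columns are surrogate points
  m <- e1071::svm(x = t(Xt), y = factor(y, levels = c(-1, 1)),
                  kernel = "linear", cost = C, scale = FALSE,
                  tolerance = tolerance, fitted = FALSE)
  alpha_y <- numeric(n)
  alpha_y[m$index] <- m$coefs
  b <- -m$rho
  first_label <- levels(factor(y, levels = c(-1, 1)))[m$labels[1]]
  if (first_label == "-1") { alpha_y <- -alpha_y; b <- -b }
  structure(list(alpha_y = alpha_y, b = b, C = C), class = "nf_svm_gram")
}

# G_cross: inner products between the training subjects (rows, in training
# order) and the subjects to score (columns)
decision_gram <- function(model, G_cross) {
  stopifnot(inherits(model, "nf_svm_gram"))
  as.vector(crossprod(G_cross, model$alpha_y)) + model$b
}
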