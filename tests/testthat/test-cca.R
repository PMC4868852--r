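test_that("input validation rejects malformed views", {
  X <- matrix(rnorm(6), 3, 2)
  expect_error(fit_cca(X, X), "at least 3")
  expect_error(fit_cca(matrix(rnorm(30), 3), matrix(rnorm(40), 4)), "shape")
  expect_error(fit_cca(matrix(rnorm(30), 3), matrix(rnorm(30), 3),
                       epsilon = -1), "epsilon")
})

test_that("identical views give unit correlations; invertible maps leave them unchanged", {
  set.seed(11)
  X1 <- matrix(rnorm(3 * 50), 3)
  m <- fit_cca(X1, X1, c = 3, epsilon = 0)
  expect_equal(m$correlations, rep(1, 3), tolerance = 1e-10)

  A <- matrix(c(2, 1, 0, 1, 3, 1, 0, 0, 1), 3, 3)
  m2 <- fit_cca(X1, A %*% X1, c = 3, epsilon = 0)
  expect_equal(m2$correlations, m$correlations, tolerance = 1e-8)
})

test_that("correlations and bases match the whitening+SVD oracle", {
  set.seed(21)
  for (trial in 1:5) {
    d <- sample(2:10, 1); n <- sample(15:50, 1)
    X1 <- matrix(rnorm(d * n), d); X2 <- matrix(rnorm(d * n), d)
    for (eps in c(0, 0.05)) {
      m <- fit_cca(X1, X2, c = d, epsilon = eps)
      o <- oracle_cca(X1, X2, epsilon = eps)
      expect_equal(m$correlations, o$correlations[seq_len(d)],
                   tolerance = 1e-8)
      # bases agree up to per-component sign
      for (i in seq_len(d)) {
        s <- sign(sum(m$B1[, i] * o$B1[, i]))
        expect_equal(m$B1[, i], s * o$B1[, i], tolerance = 1e-6)
      }
    }
  }
})

test_that("the wide-data (d > n) route agrees with the oracle on its leading components", {
  set.seed(33)
  d <- 40; n <- 15
  X1 <- matrix(rnorm(d * n), d); X2 <- matrix(rnorm(d * n), d)
  m <- fit_cca(X1, X2, c = 5, epsilon = 0.1)
  o <- oracle_cca(X1, X2, epsilon = 0.1)
  expect_equal(m$correlations, o$correlations[1:5], tolerance = 1e-8)
})

test_that("bases are orthonormal under the regularized metric and subjects can be permuted", {
  set.seed(5)
  d <- 4; n <- 30; eps <- 0.01
  X1 <- matrix(rnorm(d * n), d); X2 <- matrix(rnorm(d * n), d)
  m <- fit_cca(X1, X2, c = d, epsilon = eps)
  S11 <- tcrossprod(X1 - rowMeans(X1)) / (n - 1) + diag(eps, d)
  expect_equal(crossprod(m$B1, S11 %*% m$B1), diag(d), tolerance = 1e-10)
  S22 <- tcrossprod(X2 - rowMeans(X2)) / (n - 1) + diag(eps, d)
  expect_equal(crossprod(m$B2, S22 %*% m$B2), diag(d), tolerance = 1e-10)

  perm <- sample(n)
  mp <- fit_cca(X1[, perm], X2[, perm], c = d, epsilon = eps)
  expect_equal(mp$correlations, m$correlations, tolerance = 1e-10)
  z <- project_cca(m, X1, X2)
  zp <- project_cca(mp, X1[, perm], X2[, perm])
  expect_equal(abs(zp$Z1), abs(z$Z1[, perm]), tolerance = 1e-6)
})

test_that("projections reproduce the training correlations and the linear map", {
  set.seed(7)
  X1 <- matrix(rnorm(5 * 40), 5); X2 <- matrix(rnorm(5 * 40), 5)
  m <- fit_cca(X1, X2, c = 3, epsilon = 0)
  pr <- project_cca(m, X1, X2)
  got <- vapply(1:3, function(i) cor(pr$Z1[i, ], pr$Z2[i, ]), numeric(1))
  expect_equal(got, m$correlations, tolerance = 1e-8)

  # single column: plain matrix arithmetic
  x1 <- X1[, 3, drop = FALSE]; x2 <- X2[, 7, drop = FALSE]
  pr1 <- project_cca(m, x1, x2)
  expect_equal(pr1$Z1, crossprod(m$B1, x1 - m$mean1))
  expect_equal(pr1$Z2, crossprod(m$B2, x2 - m$mean2))
  expect_error(project_cca(m, X1[1:2, ], X2[1:2, ]), "dimension")
})

test_that("a strong shared latent yields high held-out canonical correlation", {
  lead <- vapply(1:5, function(s) {
    sp <- cohort_spec(n_per_class = 50, latent_dim = 3, shared_effect = 2,
                      modality_noise = 0.2, seed = 100 + s)
    tr <- generate_paired_vectors(sp, d = 10, draw = 1)
    te <- generate_paired_vectors(sp, d = 10, draw = 2)
    m <- fit_cca(tr$X1, tr$X2, c = 1)
    pr <- project_cca(m, te$X1, te$X2)
    cor(pr$Z1[1, ], pr$Z2[1, ])
  }, numeric(1))
  expect_gte(mean(lead), 0.8)
})

test_that("augmentation stacks blocks in order and round-trips through its metadata", {
  X1 <- matrix(1:6, 2); X2 <- matrix(7:12, 2)
  Z1 <- matrix(0.5 * (1:6), 2); Z2 <- matrix(-(1:6), 2)
  a <- augment_features(X1, X2, Z1, Z2)
  expect_equal(nrow(a$F), 8)
  expect_equal(a$F[1:2, ], X1)
  expect_equal(a$F[a$blocks$X2, ], X2)
  expect_equal(a$F[a$blocks$Z1, ], Z1)
  expect_equal(a$F[a$blocks$Z2, ], Z2)
  expect_error(augment_features(X1, X2[, 1:2], Z1, Z2), "column")

  # zero canonical blocks add no information to a linear classifier
  set.seed(2)
  Xa <- matrix(rnorm(4 * 20), 4); Xb <- matrix(rnorm(4 * 20), 4)
  y <- rep(c(1, -1), 10)
  z0 <- matrix(0, 2, 20)
  f_plain <- rbind(Xa, Xb)
  f_aug <- augment_features(Xa, Xb, z0, z0)$F
  m1 <- train_linear_svm(f_plain, y, C = 1, tolerance = 1e-8)
  m2 <- train_linear_svm(f_aug, y, C = 1, tolerance = 1e-8)
  expect_equal(svm_decision(m1, f_plain), svm_decision(m2, f_aug),
               tolerance = 1e-6)
})

test_that("model persistence round-trips exactly", {
  set.seed(3)
  X1 <- matrix(rnorm(4 * 20), 4); X2 <- matrix(rnorm(4 * 20), 4)
  m <- fit_cca(X1, X2, c = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_cca_model(m, path)
  m2 <- load_cca_model(path)
  expect_identical(unclass(m), unclass(m2)[names(unclass(m))])
})
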