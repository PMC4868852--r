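# build a small descriptor set with known locations/cells for encoder tests
fake_dset <- function(X, cells2 = NULL, slice_shape = c(32, 32)) {
  M <- nrow(X)
  ds <- structure(list(descriptors = X,
                       locations = cbind(slice = rep(1, M),
                                         row = rep(4, M), col = rep(4, M)),
                       slice_shape = slice_shape,
                       geom = dense_geometry(), cell_ids = NULL,
                       layout = NULL),
                  class = "nf_descriptors")
  ds <- assign_pyramid_cells(ds, pyramid_layout("layer1"))
  if (!is.null(cells2)) {
    ds$layout <- pyramid_layout("stacked")
    ds$cell_ids <- list(rep(1L, M), cells2)
  }
  ds
}

test_that("K-means recovers well-separated clouds and the degenerate cases", {
  set.seed(1)
  cloudA <- matrix(rnorm(6 * 3, mean = 0, sd = 0.05), 6)
  cloudB <- matrix(rnorm(6 * 3, mean = 5, sd = 0.05), 6)
  X <- rbind(cloudA, cloudB)
  cb <- fit_codebook(X, K = 2, seed = 9)
  got <- cb$centroids[order(cb$centroids[, 1]), ]
  want <- rbind(colMeans(cloudA), colMeans(cloudB))
  expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)

  # K = 1: the centroid is the global mean
  cb1 <- fit_codebook(X, K = 1, seed = 2)
  expect_equal(as.vector(cb1$centroids), colMeans(X), tolerance = 1e-10)

  # determinism
  expect_identical(fit_codebook(X, K = 2, seed = 9)$centroids, cb$centroids)

  # centroids are a local optimum: one more assignment pass changes nothing
  wa <- assign_words(cb, X)
  means <- rowsum(X, wa$cluster) / as.vector(table(wa$cluster))
  expect_equal(unname(means), cb$centroids[sort(unique(wa$cluster)), ],
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(fit_codebook(matrix(1, 5, 3), K = 2, seed = 1), "distinct")
  expect_error(fit_codebook(matrix(numeric(0), 0, 3), K = 1, seed = 1),
               "no descriptors")
})

test_that("word assignment is exact, breaks ties low, and the ANN forest agrees", {
  centroids <- rbind(c(0, 0), c(2, 0), c(0, 3))
  cb <- structure(list(centroids = centroids, K = 3L, D = 2L,
                       index = neurofuse:::build_kdforest(centroids, seed = 1)),
                  class = "nf_codebook")
  expect_equal(assign_words(cb, centroids[3, , drop = FALSE])$cluster, 3L)
  # equidistant from centroids 1 and 2 -> lowest index wins
  expect_equal(assign_words(cb, matrix(c(1, 0), 1))$cluster, 1L)
  expect_error(assign_words(cb, matrix(1, 2, 5)), "dimension")

  # agreement between exact scan and forest on realistic descriptors
  sp <- cohort_spec(n_per_class = 3, volume_shape = c(32, 32, 32), seed = 13)
  recs <- generate_paired_volumes(sp)
  pool <- do.call(rbind, lapply(recs, function(r)
    extract_dense_descriptors(r$volume_A)$descriptors))
  cbr <- fit_codebook(pool[1:1000, ], K = 64, seed = 3)
  probe <- pool[1001:1728, ]
  ex <- assign_words(cbr, probe, exact = TRUE)$cluster
  ap <- assign_words(cbr, probe, exact = FALSE)$cluster
  expect_gte(mean(ex == ap), 0.99)
  expect_true(all(table(factor(ex, 1:64)) >= 0))
  wi <- word_indicator(assign_words(cbr, probe[1:50, ]))
  expect_true(all(rowSums(wi) == 1))
})

test_that("BoVW counts are correct, additive over cells and over descriptor sets", {
  centroids <- rbind(rep(0, 4), rep(10, 4))
  cb <- structure(list(centroids = centroids, K = 2L, D = 4L,
                       index = neurofuse:::build_kdforest(centroids, seed = 1)),
                  class = "nf_codebook")
  X <- rbind(matrix(0.1, 3, 4), matrix(9.8, 2, 4))  # assignments 1,1,1,2,2
  ds <- fake_dset(X)
  h <- encode_bovw(cb, ds)
  expect_equal(h$vector, c(3, 2))
  expect_equal(sum(h$vector), nrow(X))

  # layer-2 cell histograms sum bin-wise to the layer-1 histogram,
  # and an empty cell contributes a zero block
  ds2 <- fake_dset(X, cells2 = c(1L, 1L, 2L, 2L, 4L))
  h2 <- encode_bovw(cb, ds2)
  expect_equal(length(h2$vector), 2 * (1 + 4))
  l1 <- h2$vector[1:2]
  l2 <- matrix(h2$vector[-(1:2)], nrow = 2)
  expect_equal(rowSums(l2), l1)
  expect_equal(l2[, 3], c(0, 0))

  # additivity over the concatenation of two descriptor sets
  dsA <- fake_dset(X[1:2, , drop = FALSE]); dsB <- fake_dset(X[3:5, , drop = FALSE])
  expect_equal(encode_bovw(cb, dsA)$vector + encode_bovw(cb, dsB)$vector,
               h$vector)
})

test_that("VLAD matches the direct-summation oracle and conserves residual mass", {
  set.seed(6)
  X <- matrix(rnorm(6 * 5), 6)
  cb <- fit_codebook(X, K = 2, seed = 4)
  ds <- fake_dset(X)
  wa <- assign_words(cb, ds)
  v <- encode_vlad(cb, ds)
  expect_equal(v$vector, oracle_vlad(X, wa$cluster, cb$centroids),
               tolerance = 1e-12)

  # residual/mass conservation: sum_k (v_k + count_k mu_k) = sum_m x_m
  V <- matrix(v$vector, nrow = 2, byrow = TRUE)
  cnt <- tabulate(wa$cluster, 2)
  expect_equal(colSums(V + cnt * cb$centroids), colSums(X), tolerance = 1e-10)

  # K = 1 with zero centroid: VLAD is the plain descriptor sum
  cb0 <- structure(list(centroids = matrix(0, 1, 5), K = 1L, D = 5L,
                        index = neurofuse:::build_kdforest(matrix(0, 1, 5),
                                                           seed = 1)),
                   class = "nf_codebook")
  X5 <- matrix(rnorm(20), 4)
  expect_equal(encode_vlad(cb0, fake_dset(X5))$vector, colSums(X5))

  # descriptors exactly on their centroids: zero residuals
  Xc <- cb$centroids[c(1, 2, 2), ]
  expect_equal(encode_vlad(cb, fake_dset(Xc))$vector, rep(0, 10))

  # additivity
  dsA <- fake_dset(X[1:3, ]); dsB <- fake_dset(X[4:6, ])
  expect_equal(encode_vlad(cb, dsA)$vector + encode_vlad(cb, dsB)$vector,
               v$vector, tolerance = 1e-12)

  # optional intra-block l2: every nonzero block has unit norm
  vi <- encode_vlad(cb, ds, intra_l2 = TRUE)
  Vi <- matrix(vi$vector, nrow = 2, byrow = TRUE)
  nrm <- sqrt(rowSums(Vi^2))
  expect_equal(nrm[nrm > 0], rep(1, sum(nrm > 0)), tolerance = 1e-12)
})

test_that("codebook persistence round-trips exactly", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40)
  cb <- fit_codebook(X, K = 3, seed = 2, train_fold_id = "r1_f2")
  path <- withr::local_tempfile(fileext = ".rds")
  save_codebook(cb, path)
  cb2 <- load_codebook(path)
  expect_identical(cb$centroids, cb2$centroids)
  expect_identical(cb$train_fold_id, cb2$train_fold_id)
  expect_equal(assign_words(cb2, X, exact = FALSE)$cluster,
               assign_words(cb, X, exact = FALSE)$cluster)
})
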