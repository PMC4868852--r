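test_that("cohort spec validates its fields and names the offender", {
  expect_error(cohort_spec(n_per_class = 1), "n_per_class")
  expect_error(cohort_spec(latent_dim = 0), "latent_dim")
  expect_error(cohort_spec(modality_noise = -1), "modality_noise")
  expect_error(cohort_spec(volume_shape = c(4, 32, 32)), "volume_shape")
  expect_error(generate_paired_vectors(cohort_spec(latent_dim = 6), d = 4),
               "latent_dim")
})

test_that("paired vectors are balanced, reproducible, and pass the latent through under identity mixing", {
  sp <- cohort_spec(n_per_class = 5, latent_dim = 3, seed = 4)
  pv <- generate_paired_vectors(sp, d = 6)
  expect_equal(dim(pv$X1), c(6, 20))
  expect_equal(unname(table(pv$labels)), rep(5L, 4), ignore_attr = TRUE)
  expect_identical(pv, generate_paired_vectors(sp, d = 6))

  # zero noise + identity mixing + d = latent_dim: both views equal the latent
  sp0 <- cohort_spec(n_per_class = 3, latent_dim = 4, shared_effect = 1,
                     modality_noise = 0, seed = 2)
  p0 <- generate_paired_vectors(sp0, d = 4, mixing = "identity")
  expect_equal(p0$X1, p0$X2)
})

test_that("a strong shared effect makes classes separable for a reference classifier", {
  # effect 5x the noise SD; LDA fitted on one draw, evaluated on a fresh one
  sp <- cohort_spec(n_per_class = 100, latent_dim = 3, shared_effect = 1,
                    modality_noise = 0.2, seed = 31)
  tr <- generate_paired_vectors(sp, d = 6, classes = c("AD", "NC"), draw = 1)
  te <- generate_paired_vectors(sp, d = 6, classes = c("AD", "NC"), draw = 2)
  fit <- MASS::lda(t(tr$X1), grouping = tr$labels)
  acc <- mean(predict(fit, t(te$X1))$class == te$labels)
  expect_gte(acc, 0.95)
})

test_that("a null cohort carries no shared signal between the views", {
  sp <- cohort_spec(n_per_class = 125, latent_dim = 2, shared_effect = 0,
                    modality_noise = 1, seed = 7)
  pv <- generate_paired_vectors(sp, d = 5)
  cc <- stats::cancor(t(pv$X1), t(pv$X2))
  expect_lt(max(cc$cor), 0.3)
})

test_that("volume rendering is deterministic, non-negative, and class-pure when all randomness is off", {
  sp <- cohort_spec(n_per_class = 3, volume_shape = c(16, 16, 16),
                    shared_effect = 1, modality_noise = 0.1, seed = 9)
  r1 <- generate_paired_volumes(sp)
  r2 <- generate_paired_volumes(sp)
  expect_identical(lapply(r1, function(r) r$volume_A$voxels),
                   lapply(r2, function(r) r$volume_A$voxels))
  expect_true(all(vapply(r1, function(r)
    min(r$volume_A$voxels) >= 0 && min(r$volume_B$voxels) >= 0, logical(1))))
  expect_true(all(vapply(r1, function(r)
    all(is.finite(r$volume_A$voxels)), logical(1))))

  # shared_effect = 0 and noise = 0 removes every per-subject randomness
  # source, so volumes are identical within a class
  sp0 <- cohort_spec(n_per_class = 3, volume_shape = c(16, 16, 16),
                     shared_effect = 0, modality_noise = 0, seed = 9)
  r0 <- generate_paired_volumes(sp0, classes = c("AD", "NC"))
  lab <- vapply(r0, `[[`, character(1), "label")
  ad <- r0[lab == "AD"]
  expect_identical(ad[[1]]$volume_A$voxels, ad[[2]]$volume_A$voxels)
  expect_identical(ad[[1]]$volume_B$voxels, ad[[3]]$volume_B$voxels)
})

test_that("the class-coded blob amplitude difference matches the configured shared effect", {
  se <- 0.8
  sp <- cohort_spec(n_per_class = 200, volume_shape = c(16, 16, 16),
                    shared_effect = se, modality_noise = 0, seed = 21)
  recs <- generate_paired_volumes(sp, classes = c("AD", "NC"))
  bm <- attr(recs, "blob_model")
  lat <- attr(recs, "latents")
  lab <- vapply(recs, `[[`, character(1), "label")
  # the first blob's amplitude loading is the severity axis by construction
  expect_equal(bm$A$amp_load[1, ], c(1, rep(0, sp$latent_dim - 1)))
  amp <- as.vector(bm$A$amp_load[1, ] %*% lat)
  diff <- mean(amp[lab == "AD"]) - mean(amp[lab == "NC"])
  expect_equal(diff, se, tolerance = 0.05)
})

test_that("NIfTI round trip preserves labels and voxel values", {
  sp <- cohort_spec(n_per_class = 2, volume_shape = c(12, 12, 12), seed = 3)
  recs <- generate_paired_volumes(sp, classes = c("AD", "NC"))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(recs, dir)
  expect_true(file.exists(manifest))
  man <- read.csv(manifest)
  expect_equal(names(man), c("subject_id", "label", "path_A", "path_B"))
  back <- read_cohort(manifest)
  expect_equal(length(back), length(recs))
  expect_equal(back[[1]]$label, recs[[1]]$label)
  expect_equal(as.vector(back[[3]]$volume_A$voxels),
               as.vector(recs[[3]]$volume_A$voxels), tolerance = 1e-7)
})
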