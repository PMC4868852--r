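make_volume <- function(fill, shape = c(64, 64, 4)) {
  array(fill, dim = shape)
}

test_that("geometry validation and descriptor grid arithmetic", {
  expect_error(dense_geometry(patch_size = 3, spatial_bins = 4), "multiple")
  expect_error(dense_geometry(stride = 0), "stride")
  expect_error(dense_geometry(orientation_bins = 2), "orientation_bins")

  # 64x64 slice, patch 16, stride 8 -> 7x7 positions per slice
  g <- dense_geometry(slice_step = 1)
  v <- make_volume(stats::runif(64 * 64 * 4), c(64, 64, 4))
  ds <- extract_dense_descriptors(v, g)
  expect_equal(nrow(ds$descriptors), 4 * 7 * 7)
  expect_equal(ncol(ds$descriptors), 4 * 4 * 8)
  expect_true(all(is.finite(ds$descriptors)))
})

test_that("degenerate inputs are rejected or yield zero descriptors", {
  g <- dense_geometry()
  expect_error(extract_dense_descriptors(make_volume(0, c(8, 8, 4)), g),
               "smaller than one")
  bad <- make_volume(1, c(32, 32, 4)); bad[1, 1, 1] <- NA
  expect_error(extract_dense_descriptors(bad, g), "non-finite")
  # constant intensity -> zero gradients everywhere -> zero descriptors
  ds <- extract_dense_descriptors(make_volume(3.7, c(32, 32, 4)), g)
  expect_true(all(ds$descriptors == 0))
})

test_that("a vertical step edge concentrates histogram mass in the horizontal-gradient bin", {
  g <- dense_geometry(slice_step = 1)
  v <- array(0, dim = c(64, 64, 1))
  v[, 33:64, 1] <- 1   # step along columns -> gradient in +x
  ds <- extract_dense_descriptors(v, g)
  # brute-force per-pixel histogram of the same slice identifies the bin
  oh <- oracle_orientation_histogram(v[, , 1], 8)
  dominant <- which.max(oh)
  expect_equal(sum(oh[-dominant]), 0)
  # interior descriptors put all their mass in that orientation bin
  interior <- ds$descriptors[rowSums(ds$descriptors) > 0, , drop = FALSE]
  bin_cols <- seq(dominant, ncol(interior), by = 8)
  expect_equal(rowSums(interior[, bin_cols, drop = FALSE]),
               rowSums(interior))
})

test_that("descriptors are clamped before rescaling and bounded after", {
  g <- dense_geometry()
  sp <- cohort_spec(n_per_class = 2, volume_shape = c(32, 32, 32), seed = 8)
  recs <- generate_paired_volumes(sp)
  ds <- extract_dense_descriptors(recs[[1]]$volume_A, g)
  expect_true(all(ds$descriptors >= 0))
  # after the final rescaling every component is at most clamp divided by the
  # smallest possible clamped-vector norm, and never exceeds 1
  expect_true(all(ds$descriptors <= 1))
  nrm <- sqrt(rowSums(ds$descriptors^2))
  expect_true(all(abs(nrm[nrm > 0] - 1) < 1e-12))
})

test_that("translating the volume by one stride shifts the descriptor grid", {
  g <- dense_geometry(slice_step = 1)
  set.seed(42)
  v <- array(stats::runif(64 * 64), dim = c(64, 64, 1))
  shifted <- v
  shifted[(g$stride + 1):64, , 1] <- v[1:(64 - g$stride), , 1]
  d1 <- extract_dense_descriptors(v, g)
  d2 <- extract_dense_descriptors(shifted, g)
  # row-grid position i of the original equals position i+1 of the shifted
  # volume; compare interior positions (descriptor rows are ordered with the
  # row index fastest within a slice)
  nr <- 7
  for (ci in 2:(nr - 1)) for (ri in 2:(nr - 2)) {
    expect_equal(d1$descriptors[(ci - 1) * nr + ri, ],
                 d2$descriptors[(ci - 1) * nr + ri + 1, ])
  }
})

test_that("pyramid cell assignment follows half-open intervals and is idempotent", {
  g <- dense_geometry(slice_step = 1)
  v <- make_volume(stats::runif(64 * 64 * 2), c(64, 64, 2))
  ds <- extract_dense_descriptors(v, g)
  ds <- assign_pyramid_cells(ds, pyramid_layout("stacked"))
  # layer 1: everything in the single cell
  expect_true(all(ds$cell_ids[[1]] == 1L))
  # per-layer occupancy sums to M
  expect_equal(sum(table(ds$cell_ids[[2]])), nrow(ds$descriptors))
  expect_equal(length(unique(ds$cell_ids[[2]])), 4L)
  # a descriptor centered in the top row band but right half of a 64x64
  # slice falls in cell (0,1) of the 2x2 layer
  idx <- which(ds$locations[, "row"] == 8 & ds$locations[, "col"] == 48)[1]
  expect_equal(ds$cell_ids[[2]][idx], 2L)  # row-major id of cell (0,1)
  # idempotent, and independent of descriptor values
  ds2 <- assign_pyramid_cells(ds, pyramid_layout("stacked"))
  expect_identical(ds$cell_ids, ds2$cell_ids)
  ds_scaled <- ds
  ds_scaled$descriptors <- ds$descriptors * 5
  ds3 <- assign_pyramid_cells(ds_scaled, pyramid_layout("stacked"))
  expect_identical(ds$cell_ids, ds3$cell_ids)
})
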