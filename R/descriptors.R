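#' Geometry of dense gradient-orientation descriptor sampling
#'
#' Descriptors are computed on a regular grid of square patches over 2D
#' slices of a volume (every `slice_step`-th slice along `slice_axis`).  Each
#' patch is divided into `spatial_bins x spatial_bins` cells and a
#' gradient-orientation histogram with `orientation_bins` bins is accumulated
#' per cell; the concatenated histogram is l2-scaled, clamped at `clamp` and
#' re-l2-scaled (the standard dense-SIFT scheme).
#'
#' @param patch_size patch side in pixels (multiple of `spatial_bins`).
#' @param stride grid step in pixels (>= 1).
#' @param spatial_bins spatial bins per patch axis.
#' @param orientation_bins number of orientation bins (>= 4), covering the
#'   full signed gradient direction circle.
#' @param slice_axis axis (1..3) along which 2D slices are taken.
#' @param slice_step sample every k-th slice.
#' @param clamp per-component clamp threshold after the first l2 scaling.
#' @return an object of class `nf_dense_geometry`.
#' @export
dense_geometry <- function(patch_size = 16, stride = 8, spatial_bins = 4,
                           orientation_bins = 8, slice_axis = 3,
                           slice_step = 2, clamp = 0.2) {
  if (patch_size < spatial_bins || patch_size %% spatial_bins != 0)
    stop_input("patch_size must be a multiple of spatial_bins and >= it")
  if (stride < 1) stop_input("stride must be >= 1")
  if (orientation_bins < 4) stop_input("orientation_bins must be >= 4")
  if (!slice_axis %in% 1:3) stop_input("slice_axis must be 1, 2 or 3")
  if (slice_step < 1) stop_input("slice_step must be >= 1")
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 spatial_bins = as.integer(spatial_bins),
                 orientation_bins = as.integer(orientation_bins),
                 slice_axis = as.integer(slice_axis),
                 slice_step = as.integer(slice_step),
                 clamp = clamp),
            class = "nf_dense_geometry")
}

#' Multilayer pyramid layout
#'
#' Layer 1 is always the undivided slice; layer 2 subdivides each slice into
#' disjoint cells covering it.  `mode` selects which layers feed the encoded
#' representation: only the global layer, only the subdivided layer, or both
#' stacked.
#'
#' @param mode one of `"stacked"`, `"layer1"`, `"layer2"`.
#' @param layer2 subdivision factors (rows, cols) of the second layer.
#' @return an object of class `nf_pyramid_layout` with a `layers` list of
#'   per-layer subdivision factors.
#' @export
pyramid_layout <- function(mode = c("stacked", "layer1", "layer2"),
                           layer2 = c(2, 2)) {
  mode <- match.arg(mode)
  if (length(layer2) != 2 || any(layer2 < 1))
    stop_input("layer2 must be two subdivision factors >= 1")
  layers <- switch(mode,
                   layer1 = list(c(1L, 1L)),
                   layer2 = list(as.integer(layer2)),
                   stacked = list(c(1L, 1L), as.integer(layer2)))
  structure(list(mode = mode, layers = layers), class = "nf_pyramid_layout")
}

# integral image with a zero first row/column so that the sum of rows a..b,
# cols c..d (1-based, inclusive) is S[b+1,d+1]-S[a,d+1]-S[b+1,c]+S[a,c]
integral_image <- function(m) {
  s <- apply(apply(m, 2, cumsum), 1, cumsum)  # note: transposed
  s <- t(s)
  rbind(0, cbind(0, s))
}

# descriptors for one slice; returns M x D matrix plus 0-based patch centers
dense_slice_descriptors <- function(I, geom) {
  H <- nrow(I); W <- ncol(I)
  p <- geom$patch_size; sb <- geom$spatial_bins; no <- geom$orientation_bins
  bs <- p %/% sb
  nr <- (H - p) %/% geom$stride + 1
  nc <- (W - p) %/% geom$stride + 1
  # central-difference gradients with replicate padding
  gx <- (I[, c(2:W, W), drop = FALSE] - I[, c(1, 1:(W - 1)), drop = FALSE]) / 2
  gy <- (I[c(2:H, H), , drop = FALSE] - I[c(1, 1:(H - 1)), , drop = FALSE]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi) * no), no - 1)
  ints <- lapply(0:(no - 1), function(o) integral_image(mag * (bin == o)))
  r0 <- (seq_len(nr) - 1L) * geom$stride  # 0-based top-left rows
  c0 <- (seq_len(nc) - 1L) * geom$stride
  D <- sb * sb * no
  desc <- matrix(0, nr * nc, D)
  for (i in seq_len(sb)) for (j in seq_len(sb)) {
    rlo <- r0 + (i - 1L) * bs   # 0-based start -> +1 for 1-based a
    clo <- c0 + (j - 1L) * bs
    for (o in seq_len(no)) {
      S <- ints[[o]]
      v <- S[rlo + bs + 1, clo + bs + 1, drop = FALSE] -
           S[rlo + 1, clo + bs + 1, drop = FALSE] -
           S[rlo + bs + 1, clo + 1, drop = FALSE] +
           S[rlo + 1, clo + 1, drop = FALSE]
      desc[, ((i - 1L) * sb + (j - 1L)) * no + o] <- as.vector(v)
    }
  }
  # histogram mass is nonnegative; integral-image differencing can leave
  # cancellation residue of order eps
  desc[desc < 0] <- 0
  # l2 scale, clamp, re-l2 scale; zero-gradient patches stay zero
  nrm <- sqrt(rowSums(desc^2))
  nz <- nrm > 0
  desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  desc[desc > geom$clamp] <- geom$clamp
  nrm <- sqrt(rowSums(desc^2))
  nz <- nrm > 0
  desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  centers <- cbind(row = rep(r0, nc) + p / 2, col = rep(c0, each = nr) + p / 2)
  list(descriptors = desc, centers = centers)
}

#' Extract densely sampled gradient-orientation descriptors from a volume
#'
#' 2D descriptors are computed slice-wise along the geometry's slice axis and
#' pooled into one descriptor set per volume.  The descriptor count is
#' `n_slices * (floor((H-patch)/stride)+1) * (floor((W-patch)/stride)+1)`.
#'
#' @param volume an `nf_volume` or a numeric 3D array.
#' @param geom a [dense_geometry()].
#' @return an object of class `nf_descriptors`: a matrix `descriptors`
#'   (one row per descriptor), `locations` (slice index and 0-based in-slice
#'   patch-center coordinates), the in-slice `slice_shape`, and (after
#'   [assign_pyramid_cells()]) per-layer cell ids.
#' @export
extract_dense_descriptors <- function(volume, geom = dense_geometry()) {
  vox <- if (inherits(volume, "nf_volume")) volume$voxels else volume
  if (!is.array(vox) || length(dim(vox)) != 3)
    stop_input("volume must be a 3D array or nf_volume")
  if (!all(is.finite(vox))) stop_input("volume contains non-finite voxels")
  dims <- dim(vox)
  inplane <- setdiff(1:3, geom$slice_axis)
  H <- dims[inplane[1]]; W <- dims[inplane[2]]
  if (H < geom$patch_size || W < geom$patch_size)
    stop_input("volume slices (%d x %d) are smaller than one %d-pixel patch",
               H, W, geom$patch_size)
  slices <- seq(1, dims[geom$slice_axis], by = geom$slice_step)
  parts <- lapply(slices, function(s) {
    idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    idx[[geom$slice_axis]] <- s
    I <- do.call(`[`, c(list(vox), idx, list(drop = FALSE)))
    dense_slice_descriptors(matrix(I, H, W), geom)
  })
  desc <- do.call(rbind, lapply(parts, `[[`, "descriptors"))
  locs <- do.call(rbind, lapply(seq_along(parts), function(k)
    cbind(slice = slices[k], parts[[k]]$centers)))
  structure(list(descriptors = desc, locations = locs,
                 slice_shape = c(H, W), geom = geom, cell_ids = NULL,
                 layout = NULL),
            class = "nf_descriptors")
}

#' Assign descriptors to pyramid cells
#'
#' Each descriptor belongs to the unique cell of every layer whose half-open
#' spatial interval contains its patch center.  Assignment depends only on
#' descriptor locations, never on descriptor values, and is idempotent.
#'
#' @param dset an `nf_descriptors` object.
#' @param layout a [pyramid_layout()].
#' @return `dset` with `cell_ids`: one integer vector per layer (1-based cell
#'   ids in row-major order) and the layout recorded.
#' @export
assign_pyramid_cells <- function(dset, layout = pyramid_layout()) {
  stopifnot(inherits(dset, "nf_descriptors"), inherits(layout, "nf_pyramid_layout"))
  H <- dset$slice_shape[1]; W <- dset$slice_shape[2]
  row <- dset$locations[, "row"]; col <- dset$locations[, "col"]
  dset$cell_ids <- lapply(layout$layers, function(f) {
    ri <- pmin(floor(row / (H / f[1])), f[1] - 1)
    ci <- pmin(floor(col / (W / f[2])), f[2] - 1)
    as.integer(ri * f[2] + ci + 1)
  })
  dset$layout <- layout
  dset
}
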