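#' Diagnostic labels used throughout the package
#'
#' Four clinical groups: Alzheimer's disease (AD), mild cognitive impairment
#' converters (MCI-C) and non-converters (MCI-NC), and normal controls (NC).
#' Binary tasks (AD vs NC, MCI vs NC, MCI-C vs MCI-NC) are formed downstream
#' by filtering and merging these labels.
#' @export
NF_LABELS <- c("AD", "MCI-C", "MCI-NC", "NC")

# Disease-severity code per label, on [0, 1].  The class-informative latent
# dimension shifts along this axis, so adjacent clinical stages are closer
# than the AD/NC extremes (conversion prediction is the hardest task, as in
# real cohorts).
nf_severity <- c("NC" = 0, "MCI-NC" = 1 / 3, "MCI-C" = 2 / 3, "AD" = 1)

#' Specification of a synthetic paired-modality cohort
#'
#' Defines the generative conditions for a cohort of subjects with two
#' co-registered scalar volumes per subject (modality A emulating a
#' gray-matter density map, modality B an FDG-PET intensity map).  Both
#' modalities are driven by one shared subject-level latent vector `t` that
#' carries a class-dependent shift; each modality adds its own structure and
#' noise.
#'
#' @param n_per_class subjects generated per diagnostic label (>= 2).
#' @param latent_dim dimension of the shared latent vector (>= 1).
#' @param shared_effect scale of the class-dependent shift carried by the
#'   shared latent; also scales the subject-level shared variability
#'   (within-class latent SD is `0.15 * shared_effect` per dimension).
#' @param modality_noise SD of the per-modality additive noise (>= 0).
#' @param volume_shape integer vector of 3 voxel-grid dimensions (all >= 8).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return an object of class `nf_cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 20, latent_dim = 4, shared_effect = 1,
                        modality_noise = 0.2, volume_shape = c(32, 32, 32),
                        seed = 1) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1 || n_per_class < 2)
    stop_input("invalid cohort spec: 'n_per_class' must be a single value >= 2")
  if (!is.numeric(latent_dim) || length(latent_dim) != 1 || latent_dim < 1)
    stop_input("invalid cohort spec: 'latent_dim' must be a single value >= 1")
  if (!is.numeric(shared_effect) || length(shared_effect) != 1 ||
      !is.finite(shared_effect) || shared_effect < 0)
    stop_input("invalid cohort spec: 'shared_effect' must be a finite value >= 0")
  if (!is.numeric(modality_noise) || length(modality_noise) != 1 ||
      modality_noise < 0)
    stop_input("invalid cohort spec: 'modality_noise' must be >= 0")
  if (!is.numeric(volume_shape) || length(volume_shape) != 3 ||
      any(volume_shape < 8))
    stop_input("invalid cohort spec: 'volume_shape' must be 3 dimensions, all >= 8")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop_input("invalid cohort spec: 'seed' must be a single integer")
  structure(list(n_per_class = as.integer(n_per_class),
                 latent_dim = as.integer(latent_dim),
                 shared_effect = shared_effect,
                 modality_noise = modality_noise,
                 volume_shape = as.integer(volume_shape),
                 seed = as.integer(seed)),
            class = "nf_cohort_spec")
}

# Shared latent vector for subject i: class shift along the severity axis
# (first latent coordinate) plus isotropic subject-level variation.  Both are
# scaled by shared_effect so that a null cohort (shared_effect = 0) carries no
# shared signal at all.
subject_latent <- function(spec, label, counter, draw = 1L) {
  g <- with_seed(derive_seed(derive_seed(spec$seed, 50L + draw),
                             1000L + counter), rnorm(spec$latent_dim))
  t <- 0.15 * spec$shared_effect * g
  t[1] <- t[1] + spec$shared_effect * nf_severity[[label]]
  t
}

cohort_labels <- function(spec, classes) {
  rep(classes, each = spec$n_per_class)
}

#' Generate paired low-dimensional feature matrices
#'
#' Draws two feature views of the same subjects: each column of `X1` and `X2`
#' is a modality-specific linear mixing of the subject's shared latent vector
#' plus independent Gaussian noise.  This is the light-weight counterpart of
#' [generate_paired_volumes()] used for unit testing the fusion and
#' classification stages without rendering images.
#'
#' @param spec a [cohort_spec()].
#' @param d feature dimension (>= `latent_dim`).
#' @param mixing `"random"` for seeded random orthonormal mixing matrices, or
#'   `"identity"` for the identity embedding of the latent into the first
#'   `latent_dim` feature coordinates (both views identical when noise is 0).
#' @param classes subset of [NF_LABELS] to generate (balanced,
#'   `n_per_class` each).
#' @param draw draw counter: the cohort-level structure (mixing matrices)
#'   stays fixed while the subjects are resampled, so different draws are
#'   independent samples from the same population (e.g. a held-out set).
#' @return list with `X1`, `X2` (`d x n` matrices) and `labels` (length `n`).
#' @export
generate_paired_vectors <- function(spec, d, mixing = c("random", "identity"),
                                    classes = NF_LABELS, draw = 1L) {
  stopifnot(inherits(spec, "nf_cohort_spec"))
  mixing <- match.arg(mixing)
  if (d < spec$latent_dim)
    stop_input("invalid cohort spec: feature dimension d = %d below 'latent_dim' = %d",
               d, spec$latent_dim)
  if (!all(classes %in% NF_LABELS))
    stop_input("unknown class label(s): %s",
               paste(setdiff(classes, NF_LABELS), collapse = ", "))
  L <- spec$latent_dim
  mix_one <- function(stream) {
    if (mixing == "identity") {
      M <- matrix(0, d, L); M[cbind(seq_len(L), seq_len(L))] <- 1; M
    } else {
      with_seed(derive_seed(spec$seed, stream),
                qr.Q(qr(matrix(rnorm(d * L), d, L))))
    }
  }
  M1 <- mix_one(1L); M2 <- mix_one(2L)
  labels <- cohort_labels(spec, classes)
  n <- length(labels)
  X1 <- matrix(0, d, n); X2 <- matrix(0, d, n)
  for (i in seq_len(n)) {
    t <- subject_latent(spec, labels[i], i, draw)
    eps <- with_seed(derive_seed(derive_seed(spec$seed, 60L + draw),
                                 2000L + i), rnorm(2 * d))
    X1[, i] <- M1 %*% t + spec$modality_noise * eps[seq_len(d)]
    X2[, i] <- M2 %*% t + spec$modality_noise * eps[d + seq_len(d)]
  }
  list(X1 = X1, X2 = X2, labels = labels)
}

# --- volume rendering ------------------------------------------------------

# Separable Gaussian smoothing of a 3D array (reflect-free truncated kernel,
# renormalized at the borders).
gauss_smooth_3d <- function(a, sigma = 1.2) {
  dims <- dim(a)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  smooth_axis <- function(x, axis) {
    m <- aperm(x, c(axis, setdiff(1:3, axis)))
    d <- dim(m)
    mm <- matrix(m, nrow = d[1])
    n <- d[1]
    # banded convolution with replicate padding at the edges
    out <- matrix(0, n, ncol(mm))
    for (j in -r:r) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n)
      out <- out + k[j + r + 1] * mm[src, , drop = FALSE]
    }
    dim(out) <- d
    aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

# Unit-SD smooth random field from a given seed.
smooth_field <- function(shape, seed, sigma = 1.2) {
  f <- with_seed(seed, array(rnorm(prod(shape)), dim = shape))
  f <- gauss_smooth_3d(f, sigma)
  f / stats::sd(f)
}

# Fixed per-cohort anatomy: an ellipsoidal envelope, a template texture and a
# set of anisotropic Gaussian blobs per modality.  Blob amplitudes and
# positions are driven by the shared latent; the first blob's amplitude
# loading is exactly the severity axis, so the class blob-amplitude
# difference at its center equals the configured shared effect.
blob_model <- function(spec) {
  shape <- spec$volume_shape
  L <- spec$latent_dim
  build_mod <- function(modality, stream) {
    with_seed(derive_seed(spec$seed, stream), {
      nb <- 6L
      centers <- sapply(shape, function(s) stats::runif(nb, 0.25 * s, 0.75 * s))
      sigmas  <- sapply(shape, function(s) stats::runif(nb, 0.06 * s, 0.12 * s))
      base <- stats::runif(nb, 0.8, 1.2)
      amp_load <- matrix(stats::rnorm(nb * L, sd = 0.4), nb, L)
      amp_load[1, ] <- c(1, rep(0, L - 1))
      pos_load <- array(stats::rnorm(3 * L * nb, sd = 0.6), dim = c(3, L, nb))
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      pos_load[, 1, 1] <- 1.5 * u
      list(modality = modality, centers = centers, sigmas = sigmas,
           base = base, amp_load = amp_load, pos_load = pos_load)
    })
  }
  list(A = build_mod("A", 11L), B = build_mod("B", 12L),
       texture_A = smooth_field(shape, derive_seed(spec$seed, 13L), 1.5),
       texture_B = smooth_field(shape, derive_seed(spec$seed, 14L), 1.5))
}

render_blob <- function(shape, center, sigma, amplitude) {
  ax <- lapply(1:3, function(k)
    exp(-((seq_len(shape[k]) - center[k])^2) / (2 * sigma[k]^2)))
  amplitude * (ax[[1]] %o% ax[[2]] %o% ax[[3]])
}

render_volume <- function(spec, mod, texture, t, noise_seed) {
  shape <- spec$volume_shape
  ctr <- (shape + 1) / 2
  env_ax <- lapply(1:3, function(k)
    exp(-((seq_len(shape[k]) - ctr[k])^2) / (2 * (0.3 * shape[k])^2)))
  v <- 0.25 * (env_ax[[1]] %o% env_ax[[2]] %o% env_ax[[3]])
  nb <- length(mod$base)
  for (b in seq_len(nb)) {
    a <- mod$base[b] + sum(mod$amp_load[b, ] * t)
    off <- pmin(pmax(as.vector(mod$pos_load[, , b] %*% t), -3), 3)
    v <- v + render_blob(shape, mod$centers[b, ] + off, mod$sigmas[b, ], a)
  }
  v <- v + 0.12 * texture
  if (spec$modality_noise > 0)
    v <- v + spec$modality_noise * smooth_field(shape, noise_seed, 1.2)
  v[v < 0] <- 0
  v
}

new_modality_volume <- function(modality, voxels, spacing = c(2, 2, 2)) {
  structure(list(modality = modality, voxels = voxels, spacing = spacing),
            class = "nf_volume")
}

#' Generate a synthetic cohort of paired 3D volumes
#'
#' Renders, for every subject, one volume per modality: a fixed ellipsoidal
#' envelope plus a set of anisotropic Gaussian blobs over a band-limited
#' template texture.  Blob amplitudes and positions are driven by the
#' subject's shared latent vector (identical for both modalities), so the two
#' modalities carry a common class-informative signal on top of
#' modality-specific structure and smooth additive noise.  Voxels are clipped
#' to be non-negative.
#'
#' @param spec a [cohort_spec()].
#' @param classes subset of [NF_LABELS] to generate.
#' @return a list of subject records (class `nf_subject`), each with
#'   `subject_id`, `label`, `volume_A`, `volume_B`.  The cohort-level blob
#'   model and per-subject latents are attached as attributes `blob_model`
#'   and `latents` for inspection.
#' @export
generate_paired_volumes <- function(spec, classes = NF_LABELS) {
  stopifnot(inherits(spec, "nf_cohort_spec"))
  bm <- blob_model(spec)
  labels <- cohort_labels(spec, classes)
  lat <- matrix(0, spec$latent_dim, length(labels))
  records <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    t <- subject_latent(spec, labels[i], i)
    lat[, i] <- t
    va <- render_volume(spec, bm$A, bm$texture_A, t,
                        derive_seed(spec$seed, 3000L + 2L * i))
    vb <- render_volume(spec, bm$B, bm$texture_B, t,
                        derive_seed(spec$seed, 3001L + 2L * i))
    records[[i]] <- structure(
      list(subject_id = sprintf("S%03d", i), label = labels[i],
           volume_A = new_modality_volume("A", va),
           volume_B = new_modality_volume("B", vb)),
      class = "nf_subject")
  }
  attr(records, "blob_model") <- bm
  attr(records, "latents") <- lat
  records
}

#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' @param records list of subject records from [generate_paired_volumes()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.  The manifest is a CSV with header
#'   `subject_id,label,path_A,path_B`.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    pa <- file.path(dir, paste0(r$subject_id, "_A.nii.gz"))
    pb <- file.path(dir, paste0(r$subject_id, "_B.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(r$volume_A$voxels,
                                       pixdim = r$volume_A$spacing), pa)
    RNifti::writeNifti(RNifti::asNifti(r$volume_B$voxels,
                                       pixdim = r$volume_B$spacing), pb)
    data.frame(subject_id = r$subject_id, label = r$label,
               path_A = pa, path_B = pb, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest CSV of NIfTI volume pairs
#'
#' @param manifest_path CSV with columns `subject_id,label,path_A,path_B`;
#'   relative volume paths are resolved against the manifest's directory.
#' @return list of subject records as in [generate_paired_volumes()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop_input("manifest not found: %s", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path_A", "path_B")
  if (!all(need %in% names(man)))
    stop_input("manifest must have columns %s", paste(need, collapse = ","))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  lapply(seq_len(nrow(man)), function(i) {
    va <- RNifti::readNifti(resolve(man$path_A[i]))
    vb <- RNifti::readNifti(resolve(man$path_B[i]))
    structure(list(subject_id = man$subject_id[i], label = man$label[i],
                   volume_A = new_modality_volume("A", as.array(va),
                                                  RNifti::pixdim(va)),
                   volume_B = new_modality_volume("B", as.array(vb),
                                                  RNifti::pixdim(vb))),
              class = "nf_subject")
  })
}
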