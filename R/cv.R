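# Repeated stratified cross-validated evaluation of the full pipeline.
# Everything that learns from data — codebooks, CCA bases, normalization
# statistics, SVMs and the score-fusion weight — is refit inside each
# training fold and applied unchanged to the held-out fold.

NF_REPRESENTATIONS <- c("MRI", "PET", "MRIPET", "MRIPETLF", "MRIPETHF")

#' Resolve a binary task name to positive/negative label sets
#'
#' Presets: `"AD_vs_NC"` (positive AD), `"MCI_vs_NC"` (positive MCI-C and
#' MCI-NC merged), `"MCIC_vs_MCINC"` (positive MCI-C).  A custom task is a
#' list with `positive` and `negative` label vectors.
#' @param task preset name or list.
#' @return list with `name`, `positive`, `negative`.
#' @export
task_spec <- function(task) {
  if (is.list(task)) {
    stopifnot(all(c("positive", "negative") %in% names(task)))
    return(list(name = if (!is.null(task$name)) task$name else "custom",
                positive = task$positive, negative = task$negative))
  }
  switch(task,
         AD_vs_NC = list(name = task, positive = "AD", negative = "NC"),
         MCI_vs_NC = list(name = task, positive = c("MCI-C", "MCI-NC"),
                          negative = "NC"),
         MCIC_vs_MCINC = list(name = task, positive = "MCI-C",
                              negative = "MCI-NC"),
         stop_input("unknown task '%s'", task))
}

power_norm_mat <- function(M, rho) sign(M) * abs(M)^rho

kernel_map_mat <- function(M, cfg) {
  if (cfg$kind == "linear") return(M)
  if (cfg$kind == "hellinger") return(sign(M) * sqrt(abs(M)))
  t(apply(M, 1, apply_kernel_map, cfg = cfg))
}

#' Descriptor sets (with pyramid cells) for every subject and modality
#'
#' Convenience wrapper over [extract_dense_descriptors()] and
#' [assign_pyramid_cells()]; its output can be passed to [run_repeated_cv()]
#' so descriptors are computed once and shared across tasks.
#'
#' @param records cohort subject records.
#' @param geom a [dense_geometry()].
#' @param layout a [pyramid_layout()].
#' @param modalities which per-subject volumes to process.
#' @return nested list: per modality, one `nf_descriptors` per subject.
#' @export
extract_cohort_descriptors <- function(records, geom, layout,
                                       modalities = c("A", "B")) {
  out <- lapply(modalities, function(mod) {
    lapply(records, function(r) {
      v <- r[[paste0("volume_", mod)]]
      assign_pyramid_cells(extract_dense_descriptors(v, geom), layout)
    })
  })
  names(out) <- modalities
  out
}

# subjects x features encoding matrix for one modality
encode_cohort_matrix <- function(dlist, cb, kind, intra_l2 = FALSE) {
  rows <- lapply(dlist, function(ds) {
    if (kind == "bovw") encode_bovw(cb, ds)$vector
    else encode_vlad(cb, ds, intra_l2 = intra_l2)$vector
  })
  do.call(rbind, rows)
}

# pooled training descriptors for codebook fitting, deterministically
# subsampled to at most max_pool rows
pool_train_descriptors <- function(dlist, train, max_pool, seed) {
  pool <- do.call(rbind, lapply(dlist[train], `[[`, "descriptors"))
  if (nrow(pool) > max_pool) {
    idx <- with_seed(seed, sort(sample.int(nrow(pool), max_pool)))
    pool <- pool[idx, , drop = FALSE]
  }
  pool
}

# inner C selection: one stratified inner CV on the training fold, working
# on the training-fold Gram matrix; returns the chosen cost and the pooled
# inner-validation scores at that cost (used for the fusion weight)
inner_select_C <- function(Gtr, ytr, C_grid, inner_k, seed) {
  kk <- min(inner_k, min(table(ytr)))
  if (kk < 2)
    return(list(C = 1, scores = rep(0, length(ytr)), labels = ytr))
  folds <- stratified_folds(ytr, kk, seed)
  score_mat <- matrix(NA_real_, length(ytr), length(C_grid))
  for (ci in seq_along(C_grid)) {
    for (f in seq_len(kk)) {
      tr <- folds != f
      mdl <- train_svm_gram(Gtr[tr, tr, drop = FALSE], ytr[tr],
                            C = C_grid[ci])
      score_mat[!tr, ci] <- decision_gram(mdl, Gtr[tr, !tr, drop = FALSE])
    }
  }
  acc <- colMeans(score_predict(score_mat) == ytr)
  ci <- which.max(acc)
  list(C = C_grid[ci], scores = score_mat[, ci], labels = ytr)
}

# fit the whole pipeline on one training fold and predict the test fold
fold_fit_predict <- function(records, dsets, y, train, test, config,
                             fold_seed, keep_models = FALSE) {
  reps <- config$representations
  kinds <- unique(c(if (any(reps == "MRIPETHF")) c("bovw", "vlad"),
                    if (any(reps != "MRIPETHF")) config$encoding))
  stage <- config$cca$stage
  mods <- c("A", "B")
  use_dsets <- dsets
  input_cca <- NULL

  if (stage == "input" && any(reps %in% c("MRIPETLF", "MRIPETHF"))) {
    # canonical filtering of the raw volumes: fit CCA on flattened training
    # voxels, reconstruct every subject through the canonical subspace, and
    # re-enter descriptor extraction with the two pseudo-modalities
    V <- lapply(mods, function(m) sapply(records, function(r)
      as.vector(r[[paste0("volume_", m)]]$voxels)))
    names(V) <- mods
    cm <- fit_cca(V$A[, train, drop = FALSE], V$B[, train, drop = FALSE],
                  c = config$cca$c, epsilon = config$cca$epsilon)
    pr <- project_cca(cm, V$A, V$B)
    n_tr <- length(train)
    recon <- function(Xtr, B, Z, mu) {
      Xc <- Xtr - rowMeans(Xtr)
      R <- Xc %*% (crossprod(Xc, B) / (n_tr - 1)) + cm$epsilon * B
      R %*% Z + mu
    }
    shape <- dim(records[[1]]$volume_A$voxels)
    pseudo <- list(AC = recon(V$A[, train, drop = FALSE], cm$B1, pr$Z1, cm$mean1),
                   BC = recon(V$B[, train, drop = FALSE], cm$B2, pr$Z2, cm$mean2))
    for (pm in names(pseudo)) {
      use_dsets[[pm]] <- lapply(seq_along(records), function(i)
        assign_pyramid_cells(
          extract_dense_descriptors(array(pseudo[[pm]][, i], dim = shape),
                                    config$geometry),
          config$layout))
    }
    input_cca <- cm
  }

  enc_mods <- names(use_dsets)
  enc <- list(); cbs <- list()
  si <- 0L
  for (kind in kinds) {
    enc[[kind]] <- list()
    for (mod in enc_mods) {
      si <- si + 1L
      pool <- pool_train_descriptors(use_dsets[[mod]], train,
                                     config$max_pool,
                                     derive_seed(fold_seed, 100L + si))
      cb <- fit_codebook(pool, K = config$K[[kind]],
                         seed = derive_seed(fold_seed, 200L + si))
      E <- encode_cohort_matrix(use_dsets[[mod]], cb, kind,
                                intra_l2 = config$vlad_intra_l2)
      E <- power_norm_mat(E, config$normalization$rho)
      nm <- normalize_cohort_l2al2w(E[train, , drop = FALSE],
                                    E[test, , drop = FALSE])
      Efull <- matrix(0, nrow(E), ncol(E))
      Efull[train, ] <- nm$train; Efull[test, ] <- nm$test
      enc[[kind]][[mod]] <- Efull
      cbs[[paste(kind, mod, sep = "_")]] <- cb
    }
  }

  # encoded-stage CCA between the two primary modalities, per encoding kind
  ccas <- list()
  if (stage == "encoded" && any(reps %in% c("MRIPETLF", "MRIPETHF"))) {
    for (kind in kinds) {
      cm <- fit_cca(t(enc[[kind]]$A[train, , drop = FALSE]),
                    t(enc[[kind]]$B[train, , drop = FALSE]),
                    c = config$cca$c, epsilon = config$cca$epsilon)
      ccas[[kind]] <- cm
    }
  }

  rep_features <- function(rep, kind) {
    EA <- enc[[kind]]$A; EB <- enc[[kind]]$B
    M <- switch(rep,
      MRI = EA, PET = EB, MRIPET = cbind(EA, EB),
      MRIPETLF = , MRIPETHF = {
        if (stage == "encoded") {
          pr <- project_cca(ccas[[kind]], t(EA), t(EB))
          cbind(EA, EB, t(pr$Z1), t(pr$Z2))
        } else if (stage == "input") {
          cbind(EA, EB, enc[[kind]]$AC, enc[[kind]]$BC)
        } else cbind(EA, EB)
      })
    kernel_map_mat(M, config$kernel_map)
  }

  ytr <- y[train]
  fold_models <- list(codebooks = if (keep_models) lapply(cbs, `[[`, "centroids"),
                      cca = if (keep_models) c(ccas, list(input = input_cca)))
  # all SVMs run in the Gram domain (features >> subjects); the training
  # block of each Gram matrix never touches test-subject features
  fit_one <- function(Fm, inner_seed) {
    G <- tcrossprod(Fm)
    sel <- inner_select_C(G[train, train, drop = FALSE], ytr, config$C_grid,
                          config$inner_k, inner_seed)
    mdl <- train_svm_gram(G[train, train, drop = FALSE], ytr, C = sel$C)
    list(sel = sel, model = mdl,
         test_scores = decision_gram(mdl, G[train, test, drop = FALSE]))
  }
  res <- list()
  for (rep in reps) {
    if (rep == "MRIPETHF") {
      # same inner split for both encodings so their held-out scores align
      fb <- fit_one(rep_features(rep, "bovw"), derive_seed(fold_seed, 301L))
      fv <- fit_one(rep_features(rep, "vlad"), derive_seed(fold_seed, 301L))
      alpha <- select_fusion_weight(fb$sel$scores, fv$sel$scores, ytr,
                                    config$alpha_grid)
      dv <- fuse_scores(score_set(fb$test_scores, fv$test_scores, alpha))
      if (keep_models)
        fold_models$svm[[rep]] <- list(bovw = fb$model, vlad = fv$model,
                                       alpha = alpha,
                                       C = c(bovw = fb$sel$C, vlad = fv$sel$C))
    } else {
      ft <- fit_one(rep_features(rep, config$encoding),
                    derive_seed(fold_seed, 302L))
      dv <- ft$test_scores
      if (keep_models) fold_models$svm[[rep]] <- list(model = ft$model,
                                                      C = ft$sel$C)
    }
    res[[rep]] <- compute_metrics(y[test], score_predict(dv), dv)
  }
  list(metrics = res, models = if (keep_models) fold_models)
}

#' Repeated stratified k-fold evaluation of the full pipeline
#'
#' For every repeat a fresh stratified partition is drawn; within every
#' training fold the codebooks, CCA model, normalization statistics, SVM
#' cost and fusion weight are refit from scratch and applied to the held-out
#' fold.  Metrics are aggregated as mean and SD over all `k * repeats` folds.
#' Bit-reproducible from the seed.
#'
#' @param records cohort subject records ([generate_paired_volumes()] or
#'   [read_cohort()]).
#' @param task a [task_spec()] preset name or custom list.
#' @param config an [experiment_config()].
#' @param k folds per repeat.
#' @param repeats number of repeated partitions.
#' @param seed integer seed controlling partitions and all refits.
#' @param keep_models store per-fold fitted artifacts (codebook centroids,
#'   CCA models, SVMs, fusion weights) in the report.
#' @param dsets optional precomputed [extract_cohort_descriptors()] output
#'   for these records (reused across tasks).
#' @return an `nf_eval_report`: `summary` (mean/SD per representation and
#'   metric), `folds` (per-fold metrics), seeds and fold assignments.
#' @export
run_repeated_cv <- function(records, task, config = experiment_config(),
                            k = config$cv$k, repeats = config$cv$repeats,
                            seed = config$seed, keep_models = FALSE,
                            dsets = NULL) {
  ts <- task_spec(task)
  labels <- vapply(records, `[[`, character(1), "label")
  sel <- labels %in% c(ts$positive, ts$negative)
  if (sum(sel) < k)
    stop_input("task %s keeps %d subjects, fewer than k = %d folds",
               ts$name, sum(sel), k)
  records <- records[sel]
  y <- ifelse(labels[sel] %in% ts$positive, 1, -1)
  if (length(unique(y)) < 2)
    stop_input("task %s needs both classes; only one is present", ts$name)
  if (min(table(y)) < k)
    stop_input("stratification impossible: smallest class of task %s has %d subjects for %d folds",
               ts$name, min(table(y)), k)
  if (is.null(dsets))
    dsets <- extract_cohort_descriptors(records, config$geometry, config$layout)
  else
    dsets <- lapply(dsets, function(dl) dl[sel])

  fold_rows <- list(); model_store <- list(); assignments <- list()
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, k, derive_seed(seed, 10000L + r))
    assignments[[r]] <- folds
    for (f in seq_len(k)) {
      fit <- fold_fit_predict(records, dsets, y,
                              train = which(folds != f),
                              test = which(folds == f),
                              config,
                              fold_seed = derive_seed(seed, 20000L + 100L * r + f),
                              keep_models = keep_models)
      for (rep in names(fit$metrics))
        fold_rows[[length(fold_rows) + 1]] <-
          data.frame(repeat_id = r, fold = f, representation = rep,
                     t(fit$metrics[[rep]]), stringsAsFactors = FALSE)
      if (keep_models) model_store[[sprintf("r%d_f%d", r, f)]] <- fit$models
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  metric_names <- c("ACC", "SEN", "SPEC", "BAC", "PPV", "NPV", "AUC")
  summ <- do.call(rbind, lapply(split(folds_df, folds_df$representation),
    function(g) do.call(rbind, lapply(metric_names, function(m)
      data.frame(task = ts$name, representation = g$representation[1],
                 metric = m, mean = mean(g[[m]], na.rm = TRUE),
                 sd = stats::sd(g[[m]], na.rm = TRUE),
                 stringsAsFactors = FALSE)))))
  rownames(summ) <- NULL
  structure(list(task = ts$name, representations = config$representations,
                 summary = summ, folds = folds_df, k = k, repeats = repeats,
                 seed = seed, fold_assignments = assignments,
                 models = if (keep_models) model_store),
            class = "nf_eval_report")
}

#' @export
print.nf_eval_report <- function(x, ...) {
  cat(sprintf("Repeated stratified CV report: task %s, %d x %d-fold, seed %d\n",
              x$task, x$repeats, x$k, x$seed))
  wide <- stats::reshape(x$summary, idvar = c("task", "representation"),
                         timevar = "metric", direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  for (i in seq_len(nrow(wide))) {
    cat(sprintf("  %-9s", wide$representation[i]))
    for (m in c("ACC", "SEN", "SPEC", "BAC", "PPV", "NPV", "AUC")) {
      row <- x$summary[x$summary$representation == wide$representation[i] &
                         x$summary$metric == m, ]
      cat(sprintf(" %s=%.2f±%.2f", m, row$mean, row$sd))
    }
    cat("\n")
  }
  invisible(x)
}
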