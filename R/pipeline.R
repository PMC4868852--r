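#' Experiment configuration
#'
#' One declarative object driving the whole pipeline: data source, tasks,
#' representations, descriptor geometry, pyramid layout, vocabulary sizes,
#' CCA stage and regularizer, normalization, kernel map, CV protocol and the
#' single seed from which all randomness flows.
#'
#' @param data list with either `manifest` (path to a cohort manifest CSV)
#'   or `cohort` (a [cohort_spec()] to synthesize).
#' @param tasks character vector of [task_spec()] presets.
#' @param representations subset of `MRI`, `PET`, `MRIPET` (plain
#'   concatenation), `MRIPETLF` (CCA-augmented) and `MRIPETHF`
#'   (CCA-augmented plus BoVW/VLAD score fusion).
#' @param geometry a [dense_geometry()].
#' @param layout a [pyramid_layout()].
#' @param K vocabulary sizes per encoding, list with `bovw` and `vlad`.
#' @param encoding encoding used by the non-hybrid representations
#'   (`"bovw"` or `"vlad"`).
#' @param vlad_intra_l2 per-block l2 scaling inside VLAD.
#' @param cca list with `stage` (`"encoded"`, `"input"` or `"none"`),
#'   `epsilon` and `c` (see [fit_cca()]).
#' @param normalization a [normalization_config()].
#' @param kernel_map a [kernel_map_config()]; the `kchi2`/`kjs` maps require
#'   nonnegative features, hence BoVW encoding and representations without
#'   CCA blocks.
#' @param cv list with `k` folds and `repeats`.
#' @param C_grid SVM cost grid searched on an inner split of each training
#'   fold.
#' @param inner_k inner folds for cost and fusion-weight selection.
#' @param alpha_grid fusion-weight grid.
#' @param max_pool cap on pooled training descriptors per codebook fit.
#' @param seed mandatory integer seed.
#' @param output_dir where [run_experiment()] writes reports.
#' @param cache_dir optional directory for the descriptor stage cache.
#' @return an object of class `nf_experiment_config`.
#' @export
experiment_config <- function(data = list(cohort = cohort_spec()),
                              tasks = "AD_vs_NC",
                              representations = c("MRI", "PET", "MRIPET",
                                                  "MRIPETLF", "MRIPETHF"),
                              geometry = dense_geometry(),
                              layout = pyramid_layout(),
                              K = list(bovw = 256, vlad = 64),
                              encoding = c("bovw", "vlad"),
                              vlad_intra_l2 = FALSE,
                              cca = list(stage = "encoded", epsilon = NULL,
                                         c = NULL),
                              normalization = normalization_config(),
                              kernel_map = kernel_map_config("linear"),
                              cv = list(k = 10, repeats = 10),
                              C_grid = c(0.01, 0.1, 1, 10),
                              inner_k = 5,
                              alpha_grid = seq(0, 1, by = 0.1),
                              max_pool = 50000,
                              seed = 1,
                              output_dir = "neurofuse_output",
                              cache_dir = NULL) {
  encoding <- match.arg(encoding)
  cfg <- structure(list(data = data, tasks = tasks,
                        representations = representations,
                        geometry = geometry, layout = layout, K = K,
                        encoding = encoding, vlad_intra_l2 = vlad_intra_l2,
                        cca = cca, normalization = normalization,
                        kernel_map = kernel_map, cv = cv, C_grid = C_grid,
                        inner_k = inner_k, alpha_grid = alpha_grid,
                        max_pool = max_pool, seed = seed,
                        output_dir = output_dir, cache_dir = cache_dir),
                   class = "nf_experiment_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop_input("config error: 'seed' is mandatory")
  bad <- setdiff(cfg$representations, NF_REPRESENTATIONS)
  if (length(bad) > 0)
    stop_input("config error: unknown representation(s) %s",
               paste(bad, collapse = ", "))
  if (!cfg$cca$stage %in% c("encoded", "input", "none"))
    stop_input("config error: cca$stage must be encoded, input or none")
  for (t in cfg$tasks) task_spec(t)
  if (cfg$kernel_map$kind %in% c("kchi2", "kjs")) {
    if (any(cfg$representations %in% c("MRIPETLF", "MRIPETHF")) &&
        cfg$cca$stage == "encoded")
      stop_input(paste("config error: %s kernel map requires nonnegative",
                       "features; CCA-augmented representations carry signed",
                       "canonical projections"), cfg$kernel_map$kind)
    if (cfg$encoding != "bovw")
      stop_input("config error: %s kernel map requires the nonnegative BoVW encoding",
                 cfg$kernel_map$kind)
  }
  if (!is.null(cfg$data$manifest) && !file.exists(cfg$data$manifest))
    stop_input("config error: manifest does not exist: %s", cfg$data$manifest)
  if (is.null(cfg$data$manifest) && !inherits(cfg$data$cohort, "nf_cohort_spec"))
    stop_input("config error: data must name a manifest or a cohort spec")
  if (cfg$cv$k < 2 || cfg$cv$repeats < 1)
    stop_input("config error: cv$k >= 2 and cv$repeats >= 1 required")
  cfg
}

# md5 of an arbitrary R object via its serialization (content-addressed
# cache keys and config snapshot hashes)
content_md5 <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(obj, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

config_to_list <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, config_to_list)
    attributes(out) <- list(names = names(x))
    out
  } else if (is.null(x)) NULL else unclass(x)
}

#' Read an experiment configuration from a YAML file
#'
#' Nested sections are passed through the corresponding constructors, so the
#' file is validated exactly like a config built in R.
#' @param path YAML file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$data$manifest)) args$data <- list(manifest = y$data$manifest)
  if (!is.null(y$data$cohort)) args$data <- list(
    cohort = do.call(cohort_spec, y$data$cohort))
  if (!is.null(y$geometry)) args$geometry <- do.call(dense_geometry, y$geometry)
  if (!is.null(y$layout)) args$layout <- do.call(pyramid_layout, y$layout)
  if (!is.null(y$normalization))
    args$normalization <- do.call(normalization_config, y$normalization)
  if (!is.null(y$kernel_map))
    args$kernel_map <- do.call(kernel_map_config, y$kernel_map)
  for (nm in c("tasks", "representations", "K", "encoding", "vlad_intra_l2",
               "cca", "cv", "C_grid", "inner_k", "alpha_grid", "max_pool",
               "seed", "output_dir", "cache_dir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(args$cca))
    args$cca <- utils::modifyList(list(stage = "encoded", epsilon = NULL,
                                       c = NULL), args$cca)
  do.call(experiment_config, args)
}

#' Run a configured end-to-end experiment
#'
#' Synthesizes or loads the cohort, extracts descriptors (cached when a
#' cache directory is configured), and evaluates every requested task and
#' representation under repeated stratified CV.  Writes the report files,
#' a log with per-stage timings, and a config snapshot whose hash the
#' reports reference.  Rerunning with an identical config reproduces the
#' report bit for bit.
#'
#' @param cfg an [experiment_config()] (or path to a YAML config).
#' @param dry_run validate the config and print the stage plan without
#'   computing.
#' @return invisibly, a list of `nf_eval_report` (one per task) with the
#'   output paths attached; for `dry_run`, the stage plan.
#' @export
run_experiment <- function(cfg, dry_run = FALSE) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  stopifnot(inherits(cfg, "nf_experiment_config"))
  validate_config(cfg)
  plan <- c(
    if (is.null(cfg$data$manifest)) "synthesize cohort" else
      sprintf("load cohort from %s", cfg$data$manifest),
    "extract dense descriptors + pyramid cells (A, B)",
    sprintf("per fold: fit codebooks (K_bovw=%s, K_vlad=%s), encode BoVW/VLAD",
            cfg$K$bovw, cfg$K$vlad),
    sprintf("per fold: power(rho=%.2f) + L2AL2W normalization",
            cfg$normalization$rho),
    sprintf("per fold: CCA stage '%s' + augmentation", cfg$cca$stage),
    sprintf("kernel map '%s'", cfg$kernel_map$kind),
    sprintf("linear SVM, %dx%d-fold stratified CV, tasks: %s; representations: %s",
            cfg$cv$repeats, cfg$cv$k, paste(cfg$tasks, collapse = ", "),
            paste(cfg$representations, collapse = ", ")))
  if (dry_run) {
    cat("stage plan:\n"); cat(paste0("  - ", plan, collapse = "\n"), "\n")
    return(invisible(plan))
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output_dir, "run.log")
  log_line <- function(...) cat(sprintf("[%s] INFO %s\n",
    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(...)),
    file = logf, append = TRUE)
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  records <- if (!is.null(cfg$data$manifest)) read_cohort(cfg$data$manifest)
             else generate_paired_volumes(cfg$data$cohort)
  log_line("stage data: %d subjects (%.2fs)", length(records), tic() - t0)

  t0 <- tic()
  dsets <- NULL
  if (!is.null(cfg$cache_dir)) {
    dir.create(cfg$cache_dir, showWarnings = FALSE, recursive = TRUE)
    key <- content_md5(list(ids = vapply(records, `[[`, character(1),
                                         "subject_id"),
                            vox = lapply(records, function(r)
                              sum(r$volume_A$voxels) + sum(r$volume_B$voxels)),
                            geometry = unclass(cfg$geometry),
                            layout = unclass(cfg$layout)))
    cache_file <- file.path(cfg$cache_dir, paste0("descriptors_", key, ".rds"))
    if (file.exists(cache_file)) {
      dsets <- readRDS(cache_file)
      log_line("stage descriptors: cache hit %s", basename(cache_file))
    }
  }
  if (is.null(dsets)) {
    dsets <- extract_cohort_descriptors(records, cfg$geometry, cfg$layout)
    if (!is.null(cfg$cache_dir)) saveRDS(dsets, cache_file)
  }
  log_line("stage descriptors: done (%.2fs)", tic() - t0)

  snapshot <- file.path(cfg$output_dir, "config_snapshot.yaml")
  yaml::write_yaml(config_to_list(cfg), snapshot)
  cfg_hash <- unname(tools::md5sum(snapshot))

  reports <- list()
  for (task in cfg$tasks) {
    t0 <- tic()
    reports[[task]] <- run_repeated_cv(records, task, cfg, dsets = dsets)
    log_line("stage cv task %s: done (%.2fs)", task, tic() - t0)
  }
  paths <- write_report(reports, cfg$output_dir, config_hash = cfg_hash)
  log_line("stage report: %s", paste(unlist(paths), collapse = ", "))
  attr(reports, "paths") <- paths
  attr(reports, "config_hash") <- cfg_hash
  invisible(reports)
}

#' Write evaluation reports to disk
#'
#' Emits `report.csv` (one row per task, representation and metric),
#' `report.json` (full per-fold detail, seeds and the config snapshot hash;
#' floats at full precision) and `summary.txt` (a human-readable table with
#' mean ± SD to two decimals, one column per metric).
#'
#' @param reports an `nf_eval_report` or a list of them.
#' @param outdir output directory.
#' @param config_hash hash of the config snapshot referenced by the files.
#' @return list of written paths.
#' @export
write_report <- function(reports, outdir, config_hash = NULL) {
  if (inherits(reports, "nf_eval_report")) reports <- list(reports)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary_df <- do.call(rbind, lapply(reports, `[[`, "summary"))
  rownames(summary_df) <- NULL
  csv_path <- file.path(outdir, "report.csv")
  utils::write.csv(summary_df, csv_path, row.names = FALSE)

  json_path <- file.path(outdir, "report.json")
  payload <- list(config_hash = config_hash,
                  tasks = lapply(reports, function(r)
                    list(task = r$task, k = r$k, repeats = r$repeats,
                         seed = r$seed, summary = r$summary,
                         folds = r$folds)))
  jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")

  txt_path <- file.path(outdir, "summary.txt")
  metric_names <- c("ACC", "SEN", "SPEC", "BAC", "PPV", "NPV", "AUC")
  lines <- c(sprintf("%-16s %-10s %s", "Task", "Modality",
                     paste(sprintf("%-13s", metric_names), collapse = "")))
  for (r in reports) {
    for (rep in unique(r$summary$representation)) {
      cells <- vapply(metric_names, function(m) {
        row <- r$summary[r$summary$representation == rep &
                           r$summary$metric == m, ]
        sprintf("%-13s", sprintf("%.2f±%.2f", row$mean, row$sd))
      }, character(1))
      lines <- c(lines, sprintf("%-16s %-10s %s", r$task, rep,
                                paste(cells, collapse = "")))
    }
  }
  writeLines(lines, txt_path)
  list(csv = csv_path, json = json_path, summary = txt_path)
}
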