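#' Reproducible end-to-end pipeline
#'
#' `run_pipeline()` chains generate -> preprocess -> featurize -> train ->
#' evaluate on synthetic sessions, persisting intermediates and a manifest
#' (config echo + file checksums) so that identical config + seed reproduces
#' identical metrics. `compare_settings()` trains matched models across
#' input modes (features-only, raw windows, raw + fused features) on
#' identical splits and seeds.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' A single global `seed` fans out deterministically to the stage seeds
#' (generator, split, model, baselines).
#'
#' @param repetitions repetitions per gesture for the synthetic protocol.
#' @param level granularity level the model is trained at.
#' @param fusion_mode ConvMixer fusion mode.
#' @param window_ms,step_ms segmentation geometry (window must exceed step).
#' @param sampling_rate generator sampling rate in Hz.
#' @param active_s,rest_s per-trial active and rest durations in seconds.
#' @param filter a [filter_spec()].
#' @param features a [feature_params()].
#' @param synth a [synth_params()] (its seed is overridden by the fan-out).
#' @param split_method `"window"` (stratified by window) or `"trial"`
#'   (whole trials held out, avoiding overlapping-window leakage; the
#'   recommended protocol for honest generalisation estimates).
#' @param split_fractions train/val/test fractions summing to 1.
#' @param model named list of [convmixer_config()] overrides (e.g.
#'   `list(hidden_dim = 32, depth = 2, epochs = 12)`).
#' @param run_baselines also fit the SVM / random-forest / LDA baselines.
#' @param seed global pipeline seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(repetitions = 3, level = "granular1",
                            fusion_mode = "late_concat",
                            window_ms = 250, step_ms = 50,
                            sampling_rate = 1925.9259,
                            active_s = 5, rest_s = 5,
                            filter = filter_spec(),
                            features = feature_params(),
                            synth = synth_params(),
                            split_method = c("window", "trial"),
                            split_fractions = c(0.6, 0.2, 0.2),
                            model = list(),
                            run_baselines = TRUE,
                            seed = 1L) {
  if (!(window_ms > step_ms && step_ms > 0)) {
    stop("pipeline config invalid: need window_ms > step_ms > 0", call. = FALSE)
  }
  level <- match.arg(level, GRANULARITY_LEVELS)
  if (abs(sum(split_fractions) - 1) > 1e-9 || any(split_fractions <= 0)) {
    stop("split_fractions must be positive and sum to 1", call. = FALSE)
  }
  structure(list(repetitions = repetitions, level = level,
                 fusion_mode = fusion_mode,
                 window_ms = window_ms, step_ms = step_ms,
                 sampling_rate = sampling_rate,
                 active_s = active_s, rest_s = rest_s,
                 filter = filter, features = features, synth = synth,
                 split_method = match.arg(split_method),
                 split_fractions = split_fractions,
                 model = model, run_baselines = isTRUE(run_baselines),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic fan-out of the global seed to stage seeds
.stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 100000L
  list(generator = base * 7L + 1L, split = base * 7L + 2L,
       model = base * 7L + 3L, baselines = base * 7L + 4L)
}

#' Split windows into train/validation/test
#'
#' @param labels class labels (any coding), one per window.
#' @param fractions train/val/test fractions summing to 1.
#' @param method `"window"` for a stratified per-window split, `"trial"` to
#'   assign whole trials (groups) to one split, which avoids leakage
#'   through overlapping windows.
#' @param groups trial id per window (required for `method = "trial"`).
#' @param seed split seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_windows <- function(labels, fractions = c(0.6, 0.2, 0.2),
                          method = c("window", "trial"), groups = NULL,
                          seed = 1L) {
  method <- match.arg(method)
  n <- length(labels)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  withr::with_seed(as.integer(seed), {
    if (method == "window") {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        k <- length(idx)
        n_tr <- max(1L, round(fractions[1] * k))
        n_va <- max(1L, round(fractions[2] * k))
        n_tr <- min(n_tr, k - 2L)
        out$train <- c(out$train, idx[seq_len(n_tr)])
        out$val <- c(out$val, idx[n_tr + seq_len(min(n_va, k - n_tr - 1L))])
        out$test <- c(out$test, idx[(n_tr + min(n_va, k - n_tr - 1L) + 1L):k])
      }
    } else {
      if (is.null(groups)) stop("method 'trial' needs groups", call. = FALSE)
      # stratify trials by their label so every split sees every class
      trial_tab <- unique(data.frame(g = groups, lab = labels))
      for (cl in unique(trial_tab$lab)) {
        gs <- trial_tab$g[trial_tab$lab == cl]
        gs <- gs[sample.int(length(gs))]
        k <- length(gs)
        n_tr <- max(1L, round(fractions[1] * k))
        n_tr <- min(n_tr, k - 1L)
        n_va <- max(0L, min(round(fractions[2] * k), k - n_tr - 1L))
        tr_g <- gs[seq_len(n_tr)]
        va_g <- if (n_va > 0) gs[n_tr + seq_len(n_va)] else integer(0)
        te_g <- setdiff(gs, c(tr_g, va_g))
        out$train <- c(out$train, which(groups %in% tr_g))
        out$val <- c(out$val, which(groups %in% va_g))
        out$test <- c(out$test, which(groups %in% te_g))
      }
    }
  })
  lapply(out, sort)
}

#' Generate, preprocess and featurise a synthetic dataset
#'
#' Runs the generator under the protocol plan, applies the notch and
#' Butterworth filters, segments overlapping windows and computes the
#' handcrafted features (on the filtered windows, matching the processing
#' order of the recognition pipeline).
#'
#' @param config a [pipeline_config()].
#' @return list with the `window_set`, the raw (unscaled) `features`
#'   matrix, `fine_id` labels and the protocol `plan`.
#' @export
prepare_dataset <- function(config = pipeline_config()) {
  seeds <- .stage_seeds(config$seed)
  plan <- make_protocol(config$repetitions,
                        sampling_rate = config$sampling_rate,
                        active_s = config$active_s, rest_s = config$rest_s,
                        seed = seeds$generator)
  sp <- config$synth
  sp$seed <- seeds$generator
  session <- synthesize_session(plan, sp)
  session <- preprocess_session(session, config$filter)
  windows <- segment_windows(session, config$window_ms, config$step_ms)
  feats <- feature_matrix(windows, config$features)
  list(windows = windows, features = feats,
       fine_id = windows$info$label, plan = plan)
}

.file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if missing); receives
#'   `features.csv`, `model.rds`-free weight summary, `report.json` and
#'   `manifest.json`.
#' @param verbose print stage progress.
#' @return list with the trained model, the fine and coarse
#'   `eval_report`s, baseline reports, and the run directory.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .stage_seeds(config$seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[generate+preprocess+featurize] repetitions=%d", config$repetitions)
  data <- prepare_dataset(config)
  y <- granulate(data$fine_id, config$level)
  K <- n_classes(config$level)
  write_feature_table(data$features, data$fine_id,
                      file.path(out_dir, "features.csv"))

  say("[split] method=%s", config$split_method)
  sp <- split_windows(y, config$split_fractions, config$split_method,
                      groups = data$windows$info$interval, seed = seeds$split)
  scaler <- fit_scaler(data$features[sp$train, , drop = FALSE])
  fstd <- apply_scaler(scaler, data$features)

  say("[train] level=%s fusion=%s", config$level, config$fusion_mode)
  margs <- utils::modifyList(
    list(n_classes = K, fusion_mode = config$fusion_mode,
         n_samples = dim(data$windows$samples)[2],
         n_channels = dim(data$windows$samples)[1],
         seed = seeds$model),
    config$model)
  mcfg <- do.call(convmixer_config, margs)
  use_feats <- mcfg$fusion_mode == "late_concat"
  model <- train_convmixer(
    subset_windows(data$windows, sp$train), y[sp$train], mcfg,
    train_features = if (use_feats) fstd[sp$train, , drop = FALSE],
    val_windows = subset_windows(data$windows, sp$val),
    val_labels = y[sp$val],
    val_features = if (use_feats) fstd[sp$val, , drop = FALSE],
    coarsen_to = "coarse", from_level = config$level, verbose = verbose)

  say("[evaluate] held-out test windows: %d", length(sp$test))
  reports <- evaluate_model(model, subset_windows(data$windows, sp$test),
                            y[sp$test], config$level,
                            test_features = if (use_feats) fstd[sp$test, , drop = FALSE],
                            report_coarsened = TRUE)
  baselines <- NULL
  if (config$run_baselines) {
    say("[baselines] svm / random forest / lda")
    baselines <- run_baselines(fstd[sp$train, , drop = FALSE], y[sp$train],
                               fstd[sp$test, , drop = FALSE], y[sp$test],
                               K, seed = seeds$baselines)
  }

  report <- list(
    level = config$level, fusion_mode = config$fusion_mode,
    seed = config$seed,
    n_windows = nrow(data$windows$info),
    n_train = length(sp$train), n_val = length(sp$val),
    n_test = length(sp$test),
    fine = list(accuracy = reports$fine$accuracy,
                sensitivity = reports$fine$sensitivity,
                specificity = reports$fine$specificity),
    coarse = list(accuracy = reports$coarse$accuracy,
                  sensitivity = reports$coarse$sensitivity,
                  specificity = reports$coarse$specificity),
    baselines = lapply(baselines, function(r)
      list(accuracy = r$accuracy, sensitivity = r$sensitivity,
           specificity = r$specificity)),
    train_loss = model$report$loss,
    val_accuracy = model$report$val_accuracy)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_eval_report(reports$fine, file.path(out_dir, "fine"))
  write_eval_report(reports$coarse, file.path(out_dir, "coarse"))

  manifest <- list(
    config = list(repetitions = config$repetitions, level = config$level,
                  fusion_mode = config$fusion_mode,
                  window_ms = config$window_ms, step_ms = config$step_ms,
                  sampling_rate = config$sampling_rate,
                  split_method = config$split_method, seed = config$seed,
                  model = margs),
    stage_seeds = seeds,
    checksums = .file_checksums(file.path(out_dir, c(
      "features.csv", "report.json", "fine_metrics.json",
      "fine_confusion.csv", "coarse_metrics.json", "coarse_confusion.csv"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(model = model, fine = reports$fine, coarse = reports$coarse,
                 baselines = baselines, report = report, out_dir = out_dir,
                 split = sp, data = data, scaler = scaler))
}

#' Compare input modes on identical splits and seeds
#'
#' Trains one model per requested setting -- `"features"` (dense head on the
#' 16 handcrafted features only), `"raw"` (ConvMixer on windows, no fusion)
#' and `"raw+features"` (ConvMixer with late feature fusion) -- at the given
#' granularity level, on the same split of the same synthetic dataset, and
#' scores each at the fine level and coarsened to the 4 primary categories.
#'
#' @param config a [pipeline_config()]; its `level` and model overrides are
#'   shared by all settings.
#' @param settings character vector of input modes to compare.
#' @return data frame with one row per setting: fine and coarse accuracy,
#'   sensitivity and specificity.
#' @export
compare_settings <- function(config = pipeline_config(),
                             settings = c("features", "raw", "raw+features")) {
  stopifnot(length(settings) >= 1)
  settings <- match.arg(settings, c("features", "raw", "raw+features"),
                        several.ok = TRUE)
  seeds <- .stage_seeds(config$seed)
  data <- prepare_dataset(config)
  y <- granulate(data$fine_id, config$level)
  K <- n_classes(config$level)
  sp <- split_windows(y, config$split_fractions, config$split_method,
                      groups = data$windows$info$interval, seed = seeds$split)
  scaler <- fit_scaler(data$features[sp$train, , drop = FALSE])
  fstd <- apply_scaler(scaler, data$features)

  rows <- lapply(settings, function(setting) {
    if (setting == "features") {
      model <- train_dense_head(fstd[sp$train, , drop = FALSE], y[sp$train],
                                n_classes = K, seed = seeds$model)
      rep2 <- evaluate_model(model, NULL, y[sp$test], config$level,
                             test_features = fstd[sp$test, , drop = FALSE],
                             report_coarsened = TRUE)
    } else {
      fuse <- setting == "raw+features"
      margs <- utils::modifyList(
        list(n_classes = K,
             fusion_mode = if (fuse) "late_concat" else "none",
             n_samples = dim(data$windows$samples)[2],
             n_channels = dim(data$windows$samples)[1],
             seed = seeds$model),
        config$model)
      mcfg <- do.call(convmixer_config, margs)
      model <- train_convmixer(
        subset_windows(data$windows, sp$train), y[sp$train], mcfg,
        train_features = if (fuse) fstd[sp$train, , drop = FALSE])
      rep2 <- evaluate_model(model, subset_windows(data$windows, sp$test),
                             y[sp$test], config$level,
                             test_features = if (fuse) fstd[sp$test, , drop = FALSE],
                             report_coarsened = TRUE)
    }
    data.frame(setting = setting,
               fine_accuracy = rep2$fine$accuracy,
               fine_sensitivity = rep2$fine$sensitivity,
               fine_specificity = rep2$fine$specificity,
               coarse_accuracy = rep2$coarse$accuracy,
               coarse_sensitivity = rep2$coarse$sensitivity,
               coarse_specificity = rep2$coarse$specificity)
  })
  do.call(rbind, rows)
}
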