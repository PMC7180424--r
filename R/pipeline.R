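#' Run configuration for the end-to-end pipeline
#'
#' Collects the paths and stage parameters for [run_end_to_end()].
#' Configurations round-trip through JSON (`read_run_config()` /
#' `write_run_config()`), and every pipeline output embeds the seed and
#' a hash of the configuration so runs are reproducible.
#'
#' @param manifest Path to the slide manifest CSV.
#' @param annotations Path to the ROI annotation JSON.
#' @param truth Path to the slide truth CSV (columns `slide_id`,
#'   `label`), used for calibration and evaluation.
#' @param out_dir Output directory.
#' @param patch A [patch_spec()].
#' @param train A [train_config()].
#' @param grid A [grid_spec()] (thresholds are calibrated on the train
#'   split), or `NULL` to use `thresholds` as given.
#' @param thresholds A [threshold_config()] used when `grid` is `NULL`.
#' @param balance_to Training patches per class after balancing.
#' @param n_models Ensemble size (members differ only in seed).
#' @param n_heatmaps Number of slides to render heatmap/lesion overlays
#'   for.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest, annotations, truth, out_dir,
                       patch = patch_spec(), train = train_config(),
                       grid = grid_spec(), thresholds = threshold_config(),
                       balance_to = 200L, n_models = 1L, n_heatmaps = 2L,
                       seed = 1L) {
  structure(list(manifest = manifest, annotations = annotations,
                 truth = truth, out_dir = out_dir, patch = patch,
                 train = train, grid = grid, thresholds = thresholds,
                 balance_to = as.integer(balance_to),
                 n_models = as.integer(n_models),
                 n_heatmaps = as.integer(n_heatmaps),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- if (is.null(x$grid)) NULL
  else grid_spec(x$grid$villous_grid, x$grid$ssa_grid, x$grid$objective)
  thr <- if (is.null(x$thresholds)) threshold_config()
  else threshold_config(x$thresholds$villous_threshold,
                        x$thresholds$ssa_threshold,
                        denominator = x$thresholds$denominator)
  aug <- if (is.null(x$train$augment)) NULL
  else augment_spec(x$train$augment$rotations, x$train$augment$hflip,
                    x$train$augment$vflip, x$train$augment$brightness,
                    x$train$augment$contrast, x$train$augment$saturation,
                    x$train$augment$hue)
  run_config(
    manifest = x$manifest, annotations = x$annotations, truth = x$truth,
    out_dir = x$out_dir,
    patch = patch_spec(x$patch$patch_size, x$patch$stride,
                       x$patch$extraction_downsample),
    train = train_config(x$train$epochs, x$train$initial_lr,
                         x$train$lr_decay, x$train$batch_size,
                         x$train$momentum, x$train$seed, aug, x$train$init),
    grid = grid, thresholds = thr, balance_to = x$balance_to,
    n_models = x$n_models, n_heatmaps = x$n_heatmaps, seed = x$seed)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

# csv with a provenance comment header
write_csv_stamped <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' Executes the complete data flow on an annotated cohort: extract and
#' balance training patches from the train-split slides, train the
#' patch classifier (an ensemble when `n_models > 1`), calibrate the
#' slide-rule thresholds by grid search over the train-split slides,
#' infer a diagnosis for every slide, evaluate against the truth
#' labels, and render heatmap overlays for the first few slides.  All
#' stages derive their randomness from `config$seed`; rerunning with an
#' identical configuration reproduces every output.
#'
#' Outputs written to `config$out_dir`: `patch_index.csv`,
#' `model.rds` (+ `.json` sidecar), `training_log.csv`,
#' `thresholds.json`, `diagnoses.csv`, `eval_report.csv`,
#' `eval_report.json`, `confusion.csv`, `run.json` (config + hash), and
#' `{slide_id}.heatmap.png` / `{slide_id}.lesion.png`.
#'
#' @param config A [run_config()] or path to its JSON form.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the trained `model`, calibrated
#'   `thresholds`, `diagnoses` data frame, `report` and `out_dir`.
#' @export
run_end_to_end <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed for slide '%s': %s", name, sid,
            conditionMessage(e)))
  }
  manifest <- stage("read_manifest", "-", read_manifest(config$manifest))
  annotations <- stage("read_annotations", "-",
                       read_annotations(config$annotations))
  truth <- utils::read.csv(config$truth, stringsAsFactors = FALSE)
  truth$slide_id <- as.character(truth$slide_id)

  ## -- training patches from the train split --------------------------------
  train_ids <- manifest$slide_id[manifest$split == "train"]
  say("extracting training patches from %d slides", length(train_ids))
  all_patches <- list(); all_labels <- character(); index <- list()
  for (sid in train_ids) {
    img_path <- manifest$image_path[manifest$slide_id == sid]
    ext <- stage("extract", sid, {
      img <- read_slide_image(img_path)
      extract_training_patches(img, annotations[annotations$slide_id == sid, ],
                               config$patch)
    })
    all_patches <- c(all_patches, ext$patches)
    all_labels <- c(all_labels, ext$labels)
    if (length(ext$labels) > 0)
      index[[sid]] <- data.frame(slide_id = sid, ext$origins,
                                 label = ext$labels,
                                 stringsAsFactors = FALSE)
  }
  # cohort-level class balancing, seeded
  if (!is.null(config$balance_to)) {
    sel <- with_seed(derive_seed(config$seed, 1), {
      unlist(lapply(split(seq_along(all_labels), all_labels), function(idx) {
        if (length(idx) >= config$balance_to) sample(idx, config$balance_to)
        else c(idx, sample(idx, config$balance_to - length(idx),
                           replace = TRUE))
      }), use.names = FALSE)
    })
    all_patches <- all_patches[sel]
    all_labels <- all_labels[sel]
  }
  write_csv_stamped(do.call(rbind, index),
                    file.path(config$out_dir, "patch_index.csv"),
                    hash, config$seed)

  ## -- train classifier (ensemble if requested) -----------------------------
  say("training %d model(s) on %d patches", config$n_models,
      length(all_labels))
  models <- lapply(seq_len(config$n_models), function(m) {
    cfg <- config$train
    cfg$seed <- as.integer(derive_seed(config$seed, 10 + m) %% 2147483646)
    train_patch_classifier(all_patches, all_labels, cfg)
  })
  model <- if (length(models) == 1L) models[[1L]] else patch_ensemble(models)
  if (inherits(model, "patch_cnn")) {
    save_patch_cnn(model, file.path(config$out_dir, "model.rds"))
    write_csv_stamped(model$log, file.path(config$out_dir, "training_log.csv"),
                      hash, config$seed)
  } else {
    saveRDS(model, file.path(config$out_dir, "model.rds"))
    write_csv_stamped(models[[1L]]$log,
                      file.path(config$out_dir, "training_log.csv"),
                      hash, config$seed)
  }
  rm(all_patches)

  ## -- per-slide patch counts ------------------------------------------------
  say("inferring patch counts for %d slides", nrow(manifest))
  counts <- list(); preds_by_slide <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$slide_id[i]
    preds <- stage("infer", sid,
                   slide_patch_predictions(model, manifest$image_path[i],
                                           config$patch, slide_id = sid))
    cc <- count_patch_classes(preds)
    counts[[sid]] <- data.frame(slide_id = sid, t(as.integer(cc)),
                                stringsAsFactors = FALSE)
    names(counts[[sid]]) <- c("slide_id", paste0("n_", patch_classes()))
    preds_by_slide[[sid]] <- preds
  }
  counts <- do.call(rbind, counts)

  ## -- calibrate thresholds on the train split -------------------------------
  truth_vec <- truth$label[match(counts$slide_id, truth$slide_id)]
  if (!is.null(config$grid)) {
    is_train <- counts$slide_id %in% train_ids
    say("calibrating thresholds on %d train slides", sum(is_train))
    cal <- calibrate_thresholds(counts[is_train, ], truth_vec[is_train],
                                config$grid)
    thresholds <- cal$thresholds
  } else thresholds <- config$thresholds
  write_thresholds(thresholds, file.path(config$out_dir, "thresholds.json"))

  ## -- diagnose and evaluate -------------------------------------------------
  diagnoses <- diagnose_slides(counts, thresholds)
  write_csv_stamped(diagnoses, file.path(config$out_dir, "diagnoses.csv"),
                    hash, config$seed)
  report <- eval_report(diagnoses$diagnosis, truth_vec)
  write_eval_report(report, file.path(config$out_dir, "eval_report.csv"),
                    file.path(config$out_dir, "eval_report.json"))
  write_csv_stamped(as.data.frame(report$confusion$counts),
                    file.path(config$out_dir, "confusion.csv"),
                    hash, config$seed)

  ## -- heatmaps --------------------------------------------------------------
  for (sid in utils::head(manifest$slide_id, config$n_heatmaps)) {
    img <- read_slide_image(manifest$image_path[manifest$slide_id == sid])
    write_slide_image(render_heatmap(img, preds_by_slide[[sid]]),
                      file.path(config$out_dir, paste0(sid, ".heatmap.png")))
    write_slide_image(render_lesion_mask(img, preds_by_slide[[sid]]),
                      file.path(config$out_dir, paste0(sid, ".lesion.png")))
  }
  jsonlite::write_json(list(config_hash = hash, seed = config$seed),
                       file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE)
  say("done: %s", config$out_dir)
  invisible(list(model = model, thresholds = thresholds,
                 diagnoses = diagnoses, report = report, counts = counts,
                 out_dir = config$out_dir))
}
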