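# End-to-end pipeline: phantom generation -> elastic augmentation ->
# modality-specific preprocessing -> split -> training -> evaluation ->
# statistical report. Fully reproducible from a config and a seed.

#' Build a registration dataset from phantom pairs
#'
#' Converts phantom pairs into model-resolution training items, applying
#' the elastic augmentation at the phantom's native resolution before
#' resizing (displacement targets are given at model scale and converted).
#'
#' Unsupervised items: fixed = deformed histology grayscale, moving =
#' snapshot grayscale. Supervised items: fixed = undeformed histology
#' grayscale (the registered-truth surrogate), moving = deformed snapshot
#' grayscale, label = original snapshot grayscale. Every item carries the
#' ground-truth field resampled to model scale (`true_field`), binary
#' masks (`fixed_mask`, `moving_mask`), `source_id` and `pair_id`.
#'
#' @param pairs List of phantom pairs from [generate_phantom_dataset()].
#' @param mode `"unsupervised"` or `"supervised"`.
#' @param n_variants Deformed variants per source pair.
#' @param seed Root seed for the deformation draws.
#' @param ranges Optional [deformation_ranges()] at native resolution;
#'   defaults to the reference ranges rescaled by
#'   `native width / native_ref_width`.
#' @param target_px Optional `c(low, high)`: per-variant mean displacement
#'   magnitude, in model-scale pixels (see [apply_augmentation()]).
#' @param native_ref_width Reference native width the default deformation
#'   ranges were calibrated for.
#' @return A list of training items.
#' @export
build_registration_dataset <- function(pairs,
                                       mode = c("unsupervised", "supervised"),
                                       n_variants = 1L, seed = 1L,
                                       ranges = NULL,
                                       target_px = NULL,
                                       native_ref_width = 1024) {
  mode <- match.arg(mode)
  stopifnot(length(pairs) >= 1)
  wn <- ncol(pairs[[1]]$foreground_mask)
  ranges <- ranges %||%
    rescale_deformation_ranges(deformation_ranges(), wn / native_ref_width)
  # model-scale displacement target -> native scale
  native_target <- if (is.null(target_px)) NULL else
    target_px * wn / 256
  fx <- 256 / wn
  items <- list()
  for (p in pairs) {
    pid <- p$id %||% 1L
    hn <- nrow(p$foreground_mask)
    fy <- 192 / hn
    deform_src <- if (mode == "unsupervised") "histology" else "snapshot"
    recs <- apply_augmentation(p, ranges = ranges, n_variants = n_variants,
                               seed = substream_seed(seed, "source", pid),
                               which = deform_src,
                               target_px = native_target)
    hist_gray <- histology_to_gray(p$histology_like)
    snap_gray <- snapshot_to_gray(p$snapshot_like)
    for (v in seq_along(recs)) {
      r <- recs[[v]]
      true_field <- ddf(
        fx * cpp_resize_bilinear(r$field$dx, 192L, 256L),
        fy * cpp_resize_bilinear(r$field$dy, 192L, 256L))
      it <- if (mode == "unsupervised") {
        list(fixed = resize_to_model(histology_to_gray(r$pair$histology_like)),
             moving = resize_to_model(snap_gray),
             fixed_mask = resize_image(r$deformed_mask, 192L, 256L,
                                       mode = "nearest"),
             moving_mask = resize_image(p$foreground_mask, 192L, 256L,
                                        mode = "nearest"))
      } else {
        list(fixed = resize_to_model(hist_gray),
             moving = resize_to_model(snapshot_to_gray(r$pair$snapshot_like)),
             label = resize_to_model(snap_gray),
             fixed_mask = resize_image(p$foreground_mask, 192L, 256L,
                                       mode = "nearest"),
             moving_mask = resize_image(r$deformed_mask, 192L, 256L,
                                        mode = "nearest"))
      }
      it$true_field <- true_field
      it$params <- r$params
      it$source_id <- pid
      it$pair_id <- sprintf("%d_%d", pid, v)
      items[[length(items) + 1L]] <- it
    }
  }
  items
}

.stage <- function(name, log_path, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (!is.null(log_path)) {
    line <- jsonlite::toJSON(list(stage = name,
                                  seconds = round(as.numeric(
                                    Sys.time() - t0, units = "secs"), 2),
                                  time = format(Sys.time())),
                             auto_unbox = TRUE)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  res
}

#' Run the full registration pipeline
#'
#' Executes generate -> augment -> preprocess -> split -> train ->
#' evaluate -> report on phantom data and writes all artifacts (metrics
#' CSV, comparison JSON, training histories, run log) to `out_dir`. Fully
#' reproducible from the config.
#'
#' @param config A named list or the path to a YAML file with (all
#'   optional, defaults in parentheses): `seed` (1); `phantom`: `n_pairs`
#'   (30), `image_height` (384), `image_width` (512), `n_structures` (5),
#'   `artifact_rate` (0.2); `augment`: `n_variants` (1), `target_px`
#'   (c(3, 8)); `split`: `n_train`, `n_val`, `n_test` (70/15/15% of the
#'   augmented set); `train`: `modes` (`"unsupervised"`), `epochs` (10),
#'   `steps_per_epoch` (20), `batch_size` (4), `learning_rate` (0.001),
#'   `lambda` (0.01), `bin_count` (32); `evaluate`: `masks_mode`
#'   (`"otsu"`); `write_images` (FALSE).
#' @param out_dir Artifacts directory, created if needed.
#' @return A list with the metric records per method, comparison report
#'   (when two methods were trained), fitted models and artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ddfreg_run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)

  seed <- config$seed %||% 1L
  ph <- config$phantom %||% list()
  au <- config$augment %||% list()
  tr <- config$train %||% list()
  n_pairs <- ph$n_pairs %||% 30L
  n_variants <- au$n_variants %||% 1L
  modes <- tr$modes %||% "unsupervised"

  pcfg <- phantom_config(image_height = ph$image_height %||% 384L,
                         image_width = ph$image_width %||% 512L,
                         n_structures = ph$n_structures %||% 5L,
                         artifact_rate = ph$artifact_rate %||% 0.2,
                         seed = substream_seed(seed, "phantom", 0L))
  pairs <- .stage("generate", log_path, generate_phantom_dataset(n_pairs, pcfg))
  if (isTRUE(config$write_images))
    .stage("write-images", log_path,
           write_phantom_dataset(pairs, file.path(out_dir, "phantoms")))

  n_items <- n_pairs * n_variants
  sp <- config$split %||% list()
  n_test <- sp$n_test %||% max(1L, round(0.15 * n_items / n_variants) * n_variants)
  n_val <- sp$n_val %||% max(1L, round(0.15 * n_items / n_variants) * n_variants)
  n_train <- sp$n_train %||% (n_items - n_test - n_val)
  sspec <- split_spec(n_train, n_val, n_test,
                      seed = substream_seed(seed, "split", 0L))

  target <- au$target_px %||% c(3, 8)
  models <- list(); records <- list(); histories <- list()
  for (mode in modes) {
    items <- .stage(paste0("augment-", mode), log_path,
                    build_registration_dataset(
                      pairs, mode = mode, n_variants = n_variants,
                      seed = substream_seed(seed, "augment", 0L),
                      target_px = target))
    splits <- .stage(paste0("split-", mode), log_path,
                     split_dataset(items, sspec))
    cfg <- training_config(
      mode = mode,
      loss = loss_config(
        lsim_kind = if (mode == "unsupervised") "hmi" else "mse",
        lambda_smooth = tr$lambda %||% 0.01,
        bin_count = tr$bin_count %||% 32L),
      learning_rate = tr$learning_rate %||% 0.001,
      epochs = tr$epochs %||% 10L,
      steps_per_epoch = tr$steps_per_epoch %||% 20L,
      batch_size = tr$batch_size %||% 4L,
      seed = substream_seed(seed, paste0("train-", mode), 0L))
    epoch_log <- file.path(out_dir, sprintf("history_%s.jsonl", mode))
    if (file.exists(epoch_log)) file.remove(epoch_log)
    model <- .stage(paste0("train-", mode), log_path,
                    train_registration(splits$train, cfg, val = splits$val,
                                       log_path = epoch_log))
    histories[[mode]] <- model$history
    write.csv(model$history,
              file.path(out_dir, sprintf("history_%s.csv", mode)),
              row.names = FALSE)
    save_model(model, file.path(out_dir, sprintf("model_%s.rds", mode)))
    rec <- .stage(paste0("evaluate-", mode), log_path,
                  evaluate_test_set(model, splits$test,
                                    masks_mode = (config$evaluate %||%
                                      list())$masks_mode %||% "otsu",
                                    bin_count = cfg$loss$bin_count,
                                    method = mode))
    models[[mode]] <- model
    records[[mode]] <- rec
  }

  all_rec <- do.call(rbind, records)
  metrics_path <- file.path(out_dir, "metrics.csv")
  write.csv(all_rec, metrics_path, row.names = FALSE)

  report <- NULL
  if (length(records) >= 2) {
    report <- .stage("compare", log_path, {
      list(dice = compare_methods(records[[1]], records[[2]], "dice"),
           mi = compare_methods(records[[1]], records[[2]], "mi"))
    })
  }
  summaries <- lapply(records, summarize_metrics)
  report_path <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(list(summaries = summaries, comparison = report),
                       report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  invisible(list(records = records, report = report, models = models,
                 summaries = summaries,
                 paths = list(metrics = metrics_path, report = report_path,
                              log = log_path, dir = out_dir)))
}
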