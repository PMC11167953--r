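# Test-set evaluation, method comparison, end-to-end pipeline.

zeroed_network <- function(cfg) {
  net <- build_network(cfg)
  net$layers$flow$w[] <- 0
  net$layers$flow$b[] <- 0
  net
}

eval_items <- function(n, seed = 1) {
  ds <- generate_phantom_dataset(n, phantom_config(96, 128, n_structures = 2,
                                                   artifact_rate = 0,
                                                   seed = seed))
  lapply(ds, function(p) {
    list(fixed = resize_image(histology_to_gray(p$histology_like), 32, 32),
         moving = resize_image(snapshot_to_gray(p$snapshot_like), 32, 32),
         fixed_mask = resize_image(p$foreground_mask, 32, 32,
                                   mode = "nearest"),
         moving_mask = resize_image(p$foreground_mask, 32, 32,
                                    mode = "nearest"),
         pair_id = p$id)
  })
}

tiny32 <- function(seed = 1L) {
  training_config(input_height = 32L, input_width = 32L,
                  enc = c(4L, 8L, 8L, 8L), dec = c(8L, 8L, 8L, 8L, 4L, 2L),
                  seed = seed)
}

test_that("a zero-displacement network leaves every metric unchanged", {
  net <- zeroed_network(tiny32())
  items <- eval_items(3)
  rec <- evaluate_test_set(net, items, masks_mode = "provided",
                           method = "none")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$dice_after, rec$dice_before)
  expect_equal(rec$mi_after, rec$mi_before)
})

test_that("before-metrics are method-independent for the same pairs", {
  items <- eval_items(3, seed = 2)
  r1 <- evaluate_test_set(build_network(tiny32(seed = 1)), items,
                          masks_mode = "provided", method = "a")
  r2 <- evaluate_test_set(build_network(tiny32(seed = 99)), items,
                          masks_mode = "provided", method = "b")
  expect_equal(r1$dice_before, r2$dice_before)
  expect_equal(r1$mi_before, r2$mi_before)
})

test_that("method comparison flags separated distributions and not identical ones", {
  mk <- function(vals, method) data.frame(
    pair_id = seq_along(vals), dice_before = 0.5, dice_after = vals,
    mi_before = 0.3, mi_after = vals, method = method)
  a <- mk(seq(0.90, 0.99, length.out = 12), "a")
  same <- compare_methods(a, mk(a$dice_after, "b"), "dice")
  expect_false(same$significant)
  b <- mk(seq(0.60, 0.69, length.out = 12), "b")
  sep <- compare_methods(a, b, "dice")
  expect_true(sep$significant)
  expect_lt(sep$p_value, 0.05)
  expect_equal(sep$summary_a$median, median(a$dice_after))
  expect_equal(sep$summary_b$median, median(b$dice_after))
  expect_true(sep$summary_a$median >= sep$summary_a$min &&
              sep$summary_a$median <= sep$summary_a$max)
})

test_that("the pipeline runs end to end, writes artifacts, and reruns identically", {
  cfg <- list(
    seed = 5,
    phantom = list(n_pairs = 4, image_height = 96, image_width = 128,
                   n_structures = 2, artifact_rate = 0),
    augment = list(n_variants = 1, target_px = c(2, 4)),
    split = list(n_train = 2, n_val = 1, n_test = 1),
    train = list(modes = "unsupervised", epochs = 1, steps_per_epoch = 2,
                 batch_size = 1),
    evaluate = list(masks_mode = "provided"))
  d1 <- tempfile("run1"); d2 <- tempfile("run2")
  res <- run_pipeline(cfg, d1)
  expect_true(file.exists(res$paths$metrics))
  expect_true(file.exists(res$paths$report))
  expect_true(file.exists(file.path(d1, "history_unsupervised.csv")))
  epoch_log <- readLines(file.path(d1, "history_unsupervised.jsonl"))
  expect_length(epoch_log, 1)  # one epoch trained
  expect_equal(jsonlite::fromJSON(epoch_log[1])$epoch, 1)
  rec <- read.csv(res$paths$metrics)
  expect_equal(nrow(rec), 1)
  expect_true(all(is.finite(rec$dice_after)))
  run_pipeline(cfg, d2)
  expect_identical(readLines(res$paths$metrics),
                   readLines(file.path(d2, "metrics.csv")))
})

test_that("pipeline failures name the failing stage", {
  expect_error(run_pipeline(list(phantom = list(n_pairs = 2),
                                 split = list(n_train = 99, n_val = 1,
                                              n_test = 1))),
               "stage 'split-unsupervised' failed")
})

test_that("comparison significance agrees with recomputation from saved records", {
  set.seed(33)
  mk <- function(vals, method) data.frame(
    pair_id = seq_along(vals), dice_before = 0.5, dice_after = vals,
    mi_before = 0.3, mi_after = vals + 0.1, method = method)
  a <- mk(runif(15, 0.8, 0.95), "a")
  b <- mk(runif(15, 0.75, 0.9), "b")
  rep <- compare_methods(a, b, "mi")
  csv <- tempfile(fileext = ".csv")
  write.csv(rbind(a, b), csv, row.names = FALSE)
  back <- read.csv(csv)
  redo <- mann_whitney_u(back$mi_after[back$method == "a"],
                         back$mi_after[back$method == "b"])
  expect_equal(rep$p_value, redo$p.value)
  expect_equal(rep$significant, redo$p.value <= 0.05)
})
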