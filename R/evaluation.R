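# Test-set evaluation (Dice on foreground masks, histogram MI) and
# statistical comparison of methods.

#' Evaluate a model on a test set
#'
#' For every pair computes Dice overlap of foreground masks and histogram
#' MI between fixed and moving images before registration, and between
#' fixed and warped moving after registration.
#'
#' @param model A fitted `ddf_model` (or a `ddf_network`).
#' @param test_pairs List of items with `fixed` and `moving` grayscale
#'   matrices at model resolution. With `masks_mode = "provided"`, items
#'   must also carry binary `fixed_mask` and `moving_mask` matrices; the
#'   moving mask is then warped with the predicted field
#'   (nearest-neighbour) for the after-metric.
#' @param masks_mode `"otsu"` derives masks from the images with
#'   [foreground_mask()]; `"provided"` uses the items' own masks.
#' @param bin_count MI bin count.
#' @param method Label recorded in the output (e.g. `"unsupervised"`).
#' @return A data frame with one row per pair: `pair_id`, `dice_before`,
#'   `dice_after`, `mi_before`, `mi_after`, `method`.
#' @export
evaluate_test_set <- function(model, test_pairs,
                              masks_mode = c("otsu", "provided"),
                              bin_count = 32L, method = "unsupervised") {
  masks_mode <- match.arg(masks_mode)
  if (length(test_pairs) < 1) stop2("empty test set")
  rows <- lapply(seq_along(test_pairs), function(i) {
    it <- test_pairs[[i]]
    res <- register_pair(model, it$moving, it$fixed)
    if (masks_mode == "provided") {
      fm <- it$fixed_mask; mm <- it$moving_mask
      if (is.null(fm) || is.null(mm))
        stop2("masks_mode = 'provided' requires fixed_mask and moving_mask")
      wm <- warp_image(mm, res$field, "nearest")
    } else {
      fm <- foreground_mask(it$fixed)
      mm <- foreground_mask(it$moving)
      wm <- foreground_mask(res$warped_moving)
    }
    data.frame(pair_id = it$pair_id %||% i,
               dice_before = dice_score(fm, mm),
               dice_after = dice_score(fm, wm),
               mi_before = histogram_mi(it$fixed, it$moving, bin_count),
               mi_after = histogram_mi(it$fixed, res$warped_moving,
                                       bin_count),
               method = method)
  })
  do.call(rbind, rows)
}

.metric_summary <- function(v) {
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  list(median = median(v), iqr_low = q[1], iqr_high = q[2],
       min = min(v), max = max(v))
}

#' Compare two methods' after-registration metrics
#'
#' Two-sided Mann-Whitney U test on the chosen after-metric distributions
#' of two record sets (as produced by [evaluate_test_set()]), with
#' per-method summaries (median, interquartile range, min, max) and a
#' significance flag at p <= 0.05.
#'
#' @param records_a,records_b Metric data frames from
#'   [evaluate_test_set()].
#' @param metric `"dice"` or `"mi"`.
#' @param alpha Significance level (default 0.05).
#' @return A list: `metric`, `summary_a`, `summary_b`, `u_statistic`,
#'   `p_value`, `significant`.
#' @export
compare_methods <- function(records_a, records_b, metric = c("dice", "mi"),
                            alpha = 0.05) {
  metric <- match.arg(metric)
  if (nrow(records_a) < 1 || nrow(records_b) < 1)
    stop2("both record sets must be nonempty")
  col <- paste0(metric, "_after")
  a <- records_a[[col]]; b <- records_b[[col]]
  ht <- mann_whitney_u(a, b)
  list(metric = metric,
       method_a = records_a$method[1], method_b = records_b$method[1],
       summary_a = .metric_summary(a), summary_b = .metric_summary(b),
       u_statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value <= alpha)
}

#' Summarise metric records
#'
#' Median, interquartile range and range per metric column, before and
#' after registration.
#'
#' @param records Data frame from [evaluate_test_set()].
#' @return A data frame with one row per metric/phase combination.
#' @export
summarize_metrics <- function(records) {
  cols <- c("dice_before", "dice_after", "mi_before", "mi_after")
  do.call(rbind, lapply(cols, function(cn) {
    s <- .metric_summary(records[[cn]])
    data.frame(metric = cn, median = s$median, iqr_low = s$iqr_low,
               iqr_high = s$iqr_high, min = s$min, max = s$max)
  }))
}
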