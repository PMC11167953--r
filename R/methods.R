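# S3 methods for fitted registration models.

#' @export
print.ddf_model <- function(x, ...) {
  cat(sprintf("Deformable registration model (%s)\n", x$config$mode))
  print(x$network)
  cat(sprintf("  similarity: %s, lambda = %g, %d bins\n",
              x$config$loss$lsim_kind, x$config$loss$lambda_smooth,
              x$config$loss$bin_count))
  cat(sprintf("  trained %d epochs x %d steps, batch %d, lr %g; best epoch %d\n",
              x$config$epochs, x$config$steps_per_epoch, x$config$batch_size,
              x$config$learning_rate, x$best_epoch))
  invisible(x)
}

#' Summarise a fitted registration model
#'
#' @param object A `ddf_model`.
#' @param ... Unused.
#' @return A list with the loss history summary and configuration,
#'   printed compactly.
#' @export
summary.ddf_model <- function(object, ...) {
  h <- object$history
  out <- list(
    mode = object$config$mode,
    epochs = nrow(h),
    best_epoch = object$best_epoch,
    initial_train_loss = h$train_loss[1],
    final_train_loss = h$train_loss[nrow(h)],
    best_val_loss = if (all(is.na(h$val_loss))) NA_real_
                    else min(h$val_loss, na.rm = TRUE))
  class(out) <- "summary.ddf_model"
  out
}

#' @export
print.summary.ddf_model <- function(x, ...) {
  cat(sprintf("%s registration model, %d epochs (best: %d)\n",
              x$mode, x$epochs, x$best_epoch))
  cat(sprintf("  train loss %.5f -> %.5f\n",
              x$initial_train_loss, x$final_train_loss))
  if (!is.na(x$best_val_loss))
    cat(sprintf("  best validation loss %.5f\n", x$best_val_loss))
  invisible(x)
}

#' Extract network weights
#'
#' @param object A `ddf_model`.
#' @param ... Unused.
#' @return The named list of layer weights (`w`, `b` per layer) of the
#'   best-validation network.
#' @export
coef.ddf_model <- function(object, ...) object$network$layers

#' Register image pairs with a fitted model
#'
#' @param object A `ddf_model`.
#' @param pairs Either a single item (list with `fixed` and `moving`
#'   grayscale matrices at model resolution) or a list of such items.
#' @param ... Unused.
#' @return A `registration_result` for a single item, or a list of them.
#' @export
predict.ddf_model <- function(object, pairs, ...) {
  one <- function(it) register_pair(object, it$moving, it$fixed)
  if (!is.null(pairs$fixed)) one(pairs) else lapply(pairs, one)
}

#' Plot training history
#'
#' @param x A `ddf_model`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ddf_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = c(1, 2), col = c("black", "red3"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}
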