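# Training regimes (unsupervised MI-driven and supervised MSE-driven),
# dataset splitting, and single-pair inference.

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.001, 200 epochs of 100 steps with batch size 16, input resolution
#' 256 (wide) x 192 (high). Scale `epochs`/`steps_per_epoch`/`batch_size`
#' down for desk-scale experiments.
#'
#' @param mode `"unsupervised"` (similarity = negated soft MI) or
#'   `"supervised"` (similarity = MSE against a ground-truth label image).
#' @param loss A [loss_config()]; defaults to `"hmi"` or `"mse"` according
#'   to `mode`.
#' @param learning_rate Adam learning rate.
#' @param epochs,steps_per_epoch,batch_size Training schedule.
#' @param clip_norm Global L2 gradient-norm ceiling per step; batch
#'   gradients with a larger norm are rescaled to it. Guards against the
#'   occasional loss spikes a large displacement excursion can trigger;
#'   set `Inf` to disable.
#' @param seed Root seed for initialisation and batch sampling.
#' @param input_height,input_width Model input resolution.
#' @param enc,dec Encoder/decoder channel layout (see [build_network()]).
#' @return An object of class `training_config`.
#' @export
training_config <- function(mode = c("unsupervised", "supervised"),
                            loss = NULL,
                            learning_rate = 0.001,
                            epochs = 200L, steps_per_epoch = 100L,
                            batch_size = 16L, clip_norm = 1,
                            seed = 1L,
                            input_height = 192L, input_width = 256L,
                            enc = c(16L, 32L, 32L, 32L),
                            dec = c(32L, 32L, 32L, 32L, 16L, 2L)) {
  mode <- match.arg(mode)
  loss <- loss %||%
    loss_config(lsim_kind = if (mode == "unsupervised") "hmi" else "mse")
  stopifnot(inherits(loss, "loss_config"))
  if (learning_rate <= 0) stop2("learning_rate must be positive")
  if (epochs < 1 || steps_per_epoch < 1 || batch_size < 1)
    stop2("epochs, steps_per_epoch and batch_size must be >= 1")
  if (clip_norm <= 0) stop2("clip_norm must be positive")
  structure(list(mode = mode, loss = loss, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 seed = as.integer(seed),
                 input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 enc = as.integer(enc), dec = as.integer(dec)),
            class = "training_config")
}

#' Dataset split specification
#'
#' Defaults to the 360 / 90 / 115 train / validation / test allocation of
#' a 565-image augmented set.
#'
#' @param n_train,n_val,n_test Subset sizes; must sum to the dataset size.
#' @param seed Shuffle seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(n_train = 360L, n_val = 90L, n_test = 115L,
                       seed = 1L) {
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), seed = as.integer(seed)),
            class = "split_spec")
}

#' Group-aware train/validation/test split
#'
#' Shuffles source groups (all deformed variants of one source image share
#' a `source_id`) and allocates whole groups until each subset reaches its
#' exact size. Splits are disjoint, cover the input, keep every variant of
#' a source in the same subset, and are deterministic in the seed.
#'
#' @param items A list; each element either has a `$source_id` or carries a
#'   `source_id` attribute (items without one are their own group).
#' @param spec A [split_spec()]; sizes must sum to `length(items)` and be
#'   reachable with whole groups.
#' @return A list with `train`, `val` and `test` index-subset lists of
#'   items, plus an `indices` list of integer positions.
#' @export
split_dataset <- function(items, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(items)
  if (spec$n_train + spec$n_val + spec$n_test != n)
    stop2("split sizes %d+%d+%d do not sum to the dataset size %d",
          spec$n_train, spec$n_val, spec$n_test, n)
  sid <- vapply(seq_len(n), function(i) {
    s <- items[[i]]$source_id %||% attr(items[[i]], "source_id") %||% i
    as.integer(s)
  }, 0L)
  groups <- split(seq_len(n), sid)
  ord <- with_substream(spec$seed, "split", 0L, sample(length(groups)))
  groups <- groups[ord]
  sizes <- c(train = spec$n_train, val = spec$n_val, test = spec$n_test)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  part <- 1L
  for (g in groups) {
    while (length(out[[part]]) >= sizes[part]) part <- part + 1L
    if (length(out[[part]]) + length(g) > sizes[part])
      stop2("a source group of %d variants does not fit the remaining %s slots; choose split sizes compatible with whole groups",
            length(g), names(sizes)[part])
    out[[part]] <- c(out[[part]], g)
  }
  list(train = items[out$train], val = items[out$val], test = items[out$test],
       indices = out)
}

# Per-item loss target: the fixed image (unsupervised) or the label image
# (supervised).
.loss_target <- function(item, mode) {
  if (mode == "supervised") {
    if (is.null(item$label))
      stop2("supervised training requires a $label (ground-truth) image per pair")
    item$label
  } else item$fixed
}

.pair_loss <- function(net, item, config, grad = FALSE) {
  fw <- net_forward(net, item$fixed, item$moving, keep_cache = grad)
  target <- .loss_target(item, config$mode)
  tl <- total_loss(target, item$moving, fw$field, config$loss,
                   gradient = grad)
  list(value = as.numeric(tl), fw = fw,
       gradient = if (grad) attr(tl, "gradient") else NULL)
}

#' Train a deformable registration model
#'
#' Fits the displacement-field network by stochastic gradient descent
#' (Adam) on a list of image pairs. Each item is a list with `fixed` and
#' `moving` grayscale matrices at the model resolution (and, for
#' supervised training, a `label` image, the ground truth the warped
#' moving image should reproduce). Minimises
#' `Lsim + lambda * Lsmooth`, where `Lsim` is the negated soft mutual
#' information (unsupervised) or the MSE against the label (supervised).
#' The returned model carries the weights of the epoch with the best
#' validation loss (training loss when no validation set is given).
#'
#' @param data List of training items (see above).
#' @param config A [training_config()].
#' @param val Optional list of validation items with the same structure.
#' @param log_path Optional file path: one JSON line per epoch (epoch,
#'   train/validation loss, timestamp) is appended while training.
#' @param verbose Print per-epoch losses.
#' @return An object of class `ddf_model` with elements `network`
#'   (best-validation weights), `final_network`, `config`, `history` (data
#'   frame: epoch, train_loss, val_loss) and `best_epoch`.
#' @seealso [train_unsupervised()], [train_supervised()],
#'   [register_pair()], [predict.ddf_model()]
#' @export
train_registration <- function(data, config = training_config(),
                               val = NULL, log_path = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  if (length(data) < 1) stop2("empty training dataset")
  if (config$mode == "supervised")
    for (it in data) .loss_target(it, "supervised")

  net <- build_network(config)
  state <- adam_init(net)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, net = net, epoch = 0L)

  set.seed(substream_seed(config$seed, "batches", 0L))
  for (epoch in seq_len(config$epochs)) {
    ep_losses <- numeric(config$steps_per_epoch)
    for (step in seq_len(config$steps_per_epoch)) {
      idx <- sample.int(length(data), config$batch_size, replace = TRUE)
      gsum <- NULL
      lsum <- 0
      for (i in idx) {
        pl <- .pair_loss(net, data[[i]], config, grad = TRUE)
        if (!is.finite(pl$value))
          stop2("non-finite loss (%g) at epoch %d step %d, pair %d; try a smaller learning rate or larger soft_bandwidth",
                pl$value, epoch, step, i)
        lsum <- lsum + pl$value
        dflow <- array(c(pl$gradient$dx, pl$gradient$dy),
                       dim = c(config$input_height, config$input_width, 2L))
        g <- net_backward(net, pl$fw$cache, dflow)
        gsum <- if (is.null(gsum)) g else
          mapply(function(a, b) list(w = a$w + b$w, b = a$b + b$b),
                 gsum, g, SIMPLIFY = FALSE)
      }
      gavg <- lapply(gsum, function(g)
        list(w = g$w / config$batch_size, b = g$b / config$batch_size))
      clip <- config$clip_norm %||% Inf
      if (is.finite(clip)) {
        gnorm <- sqrt(sum(vapply(gavg, function(g)
          sum(g$w^2) + sum(g$b^2), 0)))
        if (gnorm > clip) {
          s <- clip / gnorm
          gavg <- lapply(gavg, function(g)
            list(w = g$w * s, b = g$b * s))
        }
      }
      upd <- adam_step(net, gavg, state, config$learning_rate)
      net <- upd$net; state <- upd$state
      ep_losses[step] <- lsum / config$batch_size
    }
    train_loss <- mean(ep_losses)
    val_loss <- if (!is.null(val) && length(val) > 0) {
      mean(vapply(val, function(it)
        .pair_loss(net, it, config, grad = FALSE)$value, 0))
    } else NA_real_
    sel <- if (is.na(val_loss)) train_loss else val_loss
    if (sel < best$loss) best <- list(loss = sel, net = net, epoch = epoch)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (!is.null(log_path))
      cat(jsonlite::toJSON(list(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss,
                                time = format(Sys.time())),
                           auto_unbox = TRUE, digits = NA, na = "null"),
          "\n", file = log_path, append = TRUE, sep = "")
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s", epoch, train_loss,
                      if (is.na(val_loss)) "-" else sprintf("%.5f", val_loss)))
  }
  structure(list(network = best$net, final_network = net, config = config,
                 history = history, best_epoch = best$epoch),
            class = "ddf_model")
}

#' Unsupervised (mutual-information-driven) training
#'
#' Convenience wrapper around [train_registration()] with
#' `mode = "unsupervised"`: items pair a synthetically deformed histology
#' grayscale (fixed) with the snapshot grayscale (moving), and the loss is
#' `-softMI(F, M(phi)) + lambda * Lsmooth(phi)` — no ground-truth field or
#' label is used.
#'
#' @inheritParams train_registration
#' @export
train_unsupervised <- function(data, config = training_config("unsupervised"),
                               val = NULL, verbose = FALSE) {
  config$mode <- "unsupervised"
  if (config$loss$lsim_kind != "hmi")
    stop2("unsupervised training uses lsim_kind = 'hmi'")
  train_registration(data, config, val = val, verbose = verbose)
}

#' Supervised (MSE-driven) training
#'
#' Wrapper around [train_registration()] with `mode = "supervised"`:
#' items pair a registered histology grayscale (fixed) with a deformed
#' snapshot grayscale (moving), and each item's `label` is the original
#' (undeformed) snapshot grayscale; the loss is
#' `MSE(label, M(phi)) + lambda * Lsmooth(phi)`.
#'
#' @inheritParams train_registration
#' @param labels Optional list of label images, matched by position to
#'   `data`; alternatively each item may already carry `$label`.
#' @export
train_supervised <- function(data, labels = NULL,
                             config = training_config("supervised"),
                             val = NULL, verbose = FALSE) {
  config$mode <- "supervised"
  if (config$loss$lsim_kind != "mse")
    stop2("supervised training uses lsim_kind = 'mse'")
  if (!is.null(labels)) {
    if (length(labels) != length(data))
      stop2("labels (%d) and pairs (%d) differ in count",
            length(labels), length(data))
    data <- mapply(function(it, lb) { it$label <- lb; it },
                   data, labels, SIMPLIFY = FALSE)
  }
  train_registration(data, config, val = val, verbose = verbose)
}

#' Register one image pair
#'
#' A single forward pass of a (trained or fresh) network: predicts the
#' displacement field for the pair and warps the moving image; no
#' parameters are updated.
#'
#' @param network A `ddf_network` or a fitted `ddf_model`.
#' @param moving,fixed Grayscale matrices at the model resolution.
#' @return An object of class `registration_result`: list with
#'   `warped_moving`, `field` (a [ddf()]), `fixed` and `moving`.
#' @export
register_pair <- function(network, moving, fixed) {
  net <- if (inherits(network, "ddf_model")) network$network else network
  stopifnot(inherits(net, "ddf_network"))
  fw <- net_forward(net, fixed, moving)
  structure(list(warped_moving = warp_image(moving, fw$field, "bilinear"),
                 field = fw$field, fixed = fixed, moving = moving),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  mag <- sqrt(x$field$dx^2 + x$field$dy^2)
  cat(sprintf("Registration result %d x %d px\n",
              nrow(x$fixed), ncol(x$fixed)))
  cat(sprintf("  displacement: mean %.2f, max %.2f px; folded pixels: %d\n",
              mean(mag), max(mag), ddf_jacobian_negatives(x$field)))
  cat(sprintf("  MI before %.4f -> after %.4f nats\n",
              histogram_mi(x$fixed, x$moving),
              histogram_mi(x$fixed, x$warped_moving)))
  invisible(x)
}

#' Save / load a fitted registration model
#'
#' Weights and the embedded training configuration are stored with R's
#' native serialisation.
#'
#' @param model A `ddf_model` (or bare `ddf_network`).
#' @param path File path.
#' @return `load_model()` returns the stored object; `save_model()`
#'   returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ddf_model") || inherits(model, "ddf_network"))
  saveRDS(model, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
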