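# The displacement-predicting network: a small convolutional
# encoder-decoder with skip connections (VoxelMorph-style 2-D layout).
# Input is the fixed and moving grayscale images stacked as two channels;
# output is a two-channel dense displacement field (dx, dy) at input
# resolution, with the flow head initialised near zero so the initial
# transform is approximately the identity. Forward and backward passes are
# implemented directly on im2col/GEMM convolution kernels; no external
# deep-learning framework is involved.

LRELU_SLOPE <- 0.2

lrelu <- function(x) pmax(x, 0) + LRELU_SLOPE * pmin(x, 0)
lrelu_grad <- function(x, dy) dy * (LRELU_SLOPE + (1 - LRELU_SLOPE) * (x > 0))

#' Build the displacement-field network
#'
#' Encoder: stride-2 3x3 convolutions with LeakyReLU (channels `enc`,
#' default 16-32-32-32, resolutions 1/2 .. 1/16). Decoder: 3x3
#' convolutions with LeakyReLU, each followed by 2x nearest upsampling and
#' a skip concatenation with the matching encoder feature (channels the
#' first `length(dec) - 2` entries of `dec`), then a full-resolution
#' convolution (`dec[length(dec) - 1]` channels) and a linear two-channel
#' flow head. Flow-head weights are drawn with standard deviation 1e-5 and
#' zero bias, so a fresh network predicts displacements below 0.1 px.
#'
#' @param config A [training_config()]; uses the channel layout, input
#'   dimensions and seed.
#' @return An object of class `ddf_network` holding the layer weights.
#' @export
build_network <- function(config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  enc <- config$enc; dec <- config$dec
  depth <- length(enc)
  if (length(dec) != depth + 2)
    stop2("dec must have length(enc) + 2 entries (last entry = 2 flow channels)")
  if (dec[length(dec)] != 2)
    stop2("the final decoder entry must be 2 (dx, dy channels)")
  h <- config$input_height; w <- config$input_width
  if (h %% 2^depth != 0 || w %% 2^depth != 0)
    stop2("input dimensions %d x %d must be divisible by 2^%d", h, w, depth)

  cin_enc <- c(2L, enc[-depth])
  layers <- list()
  mk <- function(cin, cout, name, sd = NULL) {
    sd <- sd %||% sqrt(2 / (9 * cin))
    w_ <- with_substream(config$seed, paste0("init-", name), 0L,
                         array(rnorm(9 * cin * cout, 0, sd),
                               dim = c(3L, 3L, cin, cout)))
    list(w = w_, b = numeric(cout))
  }
  for (i in seq_len(depth))
    layers[[paste0("e", i)]] <- mk(cin_enc[i], enc[i], paste0("e", i))
  # decoder conv input channels: previous features (+ skip after upsample)
  dec_in <- c(enc[depth],
              dec[seq_len(depth - 1)] + rev(enc[-depth]),
              dec[depth] + 2L)
  for (i in seq_len(depth + 1))
    layers[[paste0("d", i)]] <- mk(dec_in[i], dec[i], paste0("d", i))
  layers[["flow"]] <- mk(dec[depth + 1], 2L, "flow", sd = 1e-5)

  structure(list(layers = layers, enc = enc, dec = dec,
                 input_height = h, input_width = w, depth = depth,
                 seed = config$seed),
            class = "ddf_network")
}

#' @export
print.ddf_network <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$w) + length(l$b), 0))
  cat(sprintf("DDF network: input %d x %d x 2, enc (%s), dec (%s), %s parameters\n",
              x$input_height, x$input_width,
              paste(x$enc, collapse = ","), paste(x$dec, collapse = ","),
              format(np, big.mark = ",")))
  invisible(x)
}

# Forward pass on one (fixed, moving) pair. Returns the flow as a ddf and,
# when keep_cache, every intermediate needed by net_backward().
net_forward <- function(net, fixed, moving, keep_cache = FALSE) {
  h <- net$input_height; w <- net$input_width
  if (!all(dim(fixed) == c(h, w)) || !all(dim(moving) == c(h, w)))
    stop2("images must be %d x %d (resize first)", h, w)
  depth <- net$depth
  x0 <- array(c(fixed, moving), dim = c(h, w, 2L))
  pre <- list(); act <- list(x0 = x0)
  a <- x0
  for (i in seq_len(depth)) {
    z <- cpp_conv2d_forward(a, net$layers[[paste0("e", i)]]$w,
                            net$layers[[paste0("e", i)]]$b, 2L)
    pre[[paste0("e", i)]] <- z
    a <- lrelu(z)
    act[[paste0("e", i)]] <- a
  }
  skips <- c(list(x0), act[paste0("e", seq_len(depth - 1))])
  ups <- list()
  for (i in seq_len(depth + 1)) {
    z <- cpp_conv2d_forward(a, net$layers[[paste0("d", i)]]$w,
                            net$layers[[paste0("d", i)]]$b, 1L)
    pre[[paste0("d", i)]] <- z
    a <- lrelu(z)
    act[[paste0("d", i)]] <- a
    if (i <= depth) {
      up <- cpp_upsample2(a)
      skip <- skips[[depth + 1 - i]]
      ups[[paste0("u", i)]] <- dim(up)
      a <- array(c(up, skip), dim = dim(up) + c(0L, 0L, dim(skip)[3]))
      act[[paste0("cat", i)]] <- a
    }
  }
  flow <- cpp_conv2d_forward(a, net$layers$flow$w, net$layers$flow$b, 1L)
  out <- list(field = ddf(matrix(flow[, , 1], h, w),
                          matrix(flow[, , 2], h, w)))
  if (keep_cache) out$cache <- list(pre = pre, act = act, ups = ups)
  out
}

# Backward pass: dflow is the loss gradient w.r.t. the two flow channels
# (H x W x 2). Returns a list of weight gradients shaped like net$layers.
#
# Skip bookkeeping: decoder step i concatenates skips[[depth + 1 - i]],
# which is encoder activation e_{depth - i} for i < depth and the raw
# input x0 for i = depth. The skip part of the concat gradient therefore
# joins the encoder chain at stage j = depth - i (and is discarded for
# the x0 skip, since the input is a leaf).
net_backward <- function(net, cache, dflow) {
  depth <- net$depth
  grads <- list()
  skipg <- vector("list", depth)
  pre <- cache$pre; act <- cache$act

  bw <- cpp_conv2d_backward(act[[paste0("d", depth + 1)]],
                            net$layers$flow$w, dflow, 1L)
  grads$flow <- list(w = bw$dw, b = bw$db)
  da <- bw$dx

  for (i in rev(seq_len(depth + 1))) {
    if (i <= depth) {
      cup <- cache$ups[[paste0("u", i)]][3]
      dup <- da[, , seq_len(cup), drop = FALSE]
      if (i < depth) skipg[[depth - i]] <- da[, , -seq_len(cup), drop = FALSE]
      da <- cpp_upsample2_backward(dup)
    }
    dz <- lrelu_grad(pre[[paste0("d", i)]], da)
    inp <- if (i == 1) act[[paste0("e", depth)]]
           else act[[paste0("cat", i - 1)]]
    bw <- cpp_conv2d_backward(inp, net$layers[[paste0("d", i)]]$w, dz, 1L)
    grads[[paste0("d", i)]] <- list(w = bw$dw, b = bw$db)
    da <- bw$dx
  }

  for (j in rev(seq_len(depth))) {
    if (j < depth && !is.null(skipg[[j]])) da <- da + skipg[[j]]
    dz <- lrelu_grad(pre[[paste0("e", j)]], da)
    inp <- if (j == 1) act$x0 else act[[paste0("e", j - 1)]]
    bw <- cpp_conv2d_backward(inp, net$layers[[paste0("e", j)]]$w, dz, 2L)
    grads[[paste0("e", j)]] <- list(w = bw$dw, b = bw$db)
    da <- bw$dx
  }
  grads
}

# --- Adam -------------------------------------------------------------

adam_init <- function(net) {
  st <- lapply(net$layers, function(l)
    list(mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
  list(t = 0L, layers = st)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(net$layers)) {
    g <- grads[[nm]]; s <- state$layers[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhat <- s$mw / (1 - beta1^t); vhat <- s$vw / (1 - beta2^t)
    net$layers[[nm]]$w <- net$layers[[nm]]$w - lr * mhat / (sqrt(vhat) + eps)
    mhatb <- s$mb / (1 - beta1^t); vhatb <- s$vb / (1 - beta2^t)
    net$layers[[nm]]$b <- net$layers[[nm]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    state$layers[[nm]] <- s
  }
  list(net = net, state = state)
}
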