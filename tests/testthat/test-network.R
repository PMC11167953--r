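# Encoder-decoder displacement network: contracts, gradients, inference.

tiny_config <- function(seed = 1L, ...) {
  training_config(input_height = 32L, input_width = 32L,
                  enc = c(4L, 8L, 8L, 8L), dec = c(8L, 8L, 8L, 8L, 4L, 2L),
                  seed = seed, ...)
}

test_that("network output obeys the shape and near-identity-init contracts", {
  cfg <- tiny_config(seed = 5)
  net <- build_network(cfg)
  set.seed(1)
  fx <- matrix(runif(32 * 32), 32)
  mv <- matrix(runif(32 * 32), 32)
  fw <- ddfreg:::net_forward(net, fx, mv)
  expect_equal(dim(fw$field$dx), c(32L, 32L))
  expect_lt(max(abs(fw$field$dx), abs(fw$field$dy)), 0.1)
  # deterministic initialisation
  expect_identical(build_network(cfg)$layers, net$layers)
  # distinct seeds give distinct weights
  expect_false(identical(build_network(tiny_config(seed = 6))$layers,
                         net$layers))
  expect_error(build_network(training_config(input_height = 100L)),
               "divisible")
})

test_that("backprop through the full network matches finite differences", {
  cfg <- tiny_config(seed = 2)
  net <- build_network(cfg)
  # give the flow head real weights so every layer receives signal
  net$layers$flow$w[] <- ddfreg:::with_substream(3, "bump", 0L,
    rnorm(length(net$layers$flow$w), 0, 0.05))
  set.seed(3)
  fx <- matrix(runif(32 * 32), 32)
  mv <- matrix(runif(32 * 32), 32)
  lcfg <- loss_config("mse", lambda_smooth = 0.02)
  lossfn <- function(n) {
    fw <- ddfreg:::net_forward(n, fx, mv)
    as.numeric(total_loss(fx, mv, fw$field, lcfg))
  }
  fw <- ddfreg:::net_forward(net, fx, mv, keep_cache = TRUE)
  tl <- total_loss(fx, mv, fw$field, lcfg, gradient = TRUE)
  g <- attr(tl, "gradient")
  grads <- ddfreg:::net_backward(net, fw$cache,
                                 array(c(g$dx, g$dy), dim = c(32, 32, 2)))
  eps <- 1e-6
  set.seed(4)
  for (nm in names(net$layers)) {
    for (rep in 1:4) {
      i <- sample(length(net$layers[[nm]]$w), 1)
      n1 <- net; n1$layers[[nm]]$w[i] <- n1$layers[[nm]]$w[i] + eps
      n2 <- net; n2$layers[[nm]]$w[i] <- n2$layers[[nm]]$w[i] - eps
      num <- (lossfn(n1) - lossfn(n2)) / (2 * eps)
      ana <- grads[[nm]]$w[i]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("register_pair is inference only and is close to the identity at init", {
  cfg <- tiny_config(seed = 9)
  net <- build_network(cfg)
  set.seed(5)
  fx <- matrix(runif(32 * 32), 32)
  mv <- matrix(runif(32 * 32), 32)
  res <- register_pair(net, mv, fx)
  expect_s3_class(res, "registration_result")
  expect_lt(max(abs(res$warped_moving - mv)), 1e-2)
  expect_error(register_pair(net, matrix(0.5, 16, 16), fx), "resize")
  # predicted field serialises and round-trips losslessly
  path <- tempfile(fileext = ".rds")
  write_ddf(res$field, path)
  expect_equal(read_ddf(path)$dx, res$field$dx)
})

test_that("supervised single-pair overfit drives MSE toward zero", {
  # learnable toy: moving is a small known warp of the label
  set.seed(6)
  p <- generate_phantom_pair(phantom_config(64, 64, n_structures = 2,
                                            artifact_rate = 0, seed = 21))
  label <- resize_image(snapshot_to_gray(p$snapshot_like), 32, 32)
  truef <- generate_random_ddf(32, 32, deformation_params(4, 2, 15, seed = 2))
  item <- list(fixed = resize_image(histology_to_gray(p$histology_like),
                                    32, 32),
               moving = warp_image(label, truef), label = label)
  cfg <- tiny_config(seed = 7, mode = "supervised",
                     loss = loss_config("mse", lambda_smooth = 0.001),
                     learning_rate = 0.01, epochs = 5, steps_per_epoch = 20,
                     batch_size = 1)
  model <- train_supervised(list(item), config = cfg)
  h <- model$history
  expect_true(all(diff(h$train_loss) < 0))   # strict decrease over 5 epochs
  res <- predict(model, item)
  expect_lt(mse_loss(item$label, res$warped_moving),
            mse_loss(item$label, item$moving))
})

test_that("training is reproducible and validates its inputs", {
  set.seed(8)
  mk_item <- function(s) {
    list(fixed = matrix(runif(32 * 32), 32),
         moving = matrix(runif(32 * 32), 32))
  }
  items <- lapply(1:3, mk_item)
  cfg <- tiny_config(seed = 11, epochs = 2, steps_per_epoch = 3,
                     batch_size = 2)
  m1 <- train_unsupervised(items, config = cfg)
  m2 <- train_unsupervised(items, config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$network$layers, m2$network$layers)
  expect_error(train_registration(list(), cfg), "empty")
  expect_error(train_supervised(items, labels = list(matrix(0, 2, 2))),
               "differ in count")
})

test_that("group-aware splitting reproduces the 360/90/115 allocation", {
  items <- lapply(1:565, function(i)
    list(id = i, source_id = ((i - 1) %/% 5) + 1))
  sp <- split_dataset(items, split_spec(360, 90, 115, seed = 3))
  expect_length(sp$train, 360)
  expect_length(sp$val, 90)
  expect_length(sp$test, 115)
  idx <- sp$indices
  expect_equal(sort(c(idx$train, idx$val, idx$test)), 1:565)
  expect_length(intersect(idx$train, idx$test), 0)
  # all variants of any source stay together, across many reshuffles
  for (s in 1:100) {
    sp2 <- split_dataset(items, split_spec(360, 90, 115, seed = s))
    member <- integer(565)
    member[sp2$indices$train] <- 1L
    member[sp2$indices$val] <- 2L
    member[sp2$indices$test] <- 3L
    src7 <- which(vapply(items, `[[`, 0, "source_id") == 7)
    expect_length(unique(member[src7]), 1)
  }
  expect_error(split_dataset(items, split_spec(300, 90, 115)), "sum")
  expect_error(split_dataset(items, split_spec(358, 92, 115, seed = 1)),
               "whole groups")
})
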