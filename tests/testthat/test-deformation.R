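# Random smooth displacement fields, warping, augmentation, serialisation.

test_that("random DDF: zero alpha, exact linearity in alpha, determinism", {
  p0 <- deformation_params(sigma = 5, alpha = 0, filter_size = 21, seed = 2)
  f0 <- generate_random_ddf(40, 50, p0)
  expect_true(all(f0$dx == 0) && all(f0$dy == 0))
  pa <- deformation_params(5, 100, 21, seed = 2)
  pb <- deformation_params(5, 200, 21, seed = 2)
  fa <- generate_random_ddf(40, 50, pa)
  fb <- generate_random_ddf(40, 50, pb)
  expect_equal(fb$dx, 2 * fa$dx)
  expect_equal(fb$dy, 2 * fa$dy)
  expect_identical(generate_random_ddf(40, 50, pa)$dx, fa$dx)
})

test_that("smoothed field matches the direct-convolution oracle on 64x64", {
  set.seed(30)
  params <- deformation_params(sigma = 8, alpha = 500, filter_size = 33,
                               seed = 5)
  f <- generate_random_ddf(64, 64, params)
  # regenerate the same uniform draw the implementation used
  ux <- ddfreg:::with_substream(5, "field-x", 0L,
                                matrix(runif(64 * 64, -1, 1), 64, 64))
  oracle <- 500 * oracle_gauss_conv(ux, 8, 33)
  expect_lt(max(abs(f$dx - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("field smoothness increases with sigma", {
  # fixed seed, alpha and filter (large enough to hold the widest kernel)
  roughness <- vapply(c(10, 30, 70), function(s) {
    f <- generate_random_ddf(288, 288,
                             deformation_params(s, 1000, 281, seed = 9))
    max(abs(diff(f$dx)), abs(diff(t(f$dx))))
  }, 0)
  expect_true(all(diff(roughness) < 0))
})

test_that("parameter sampling respects ranges and determinism", {
  rg <- deformation_ranges(c(70, 70), c(11000, 11000), c(351, 351))
  p <- sample_deformation_params(rg, rng_seed = 1)
  expect_equal(p$sigma, 70)
  expect_equal(p$alpha, 11000)
  expect_equal(p$filter_size, 351L)
  draws <- lapply(1:1000, function(i)
    sample_deformation_params(deformation_ranges(), rng_seed = i))
  sig <- vapply(draws, `[[`, 0, "sigma")
  alp <- vapply(draws, `[[`, 0, "alpha")
  fil <- vapply(draws, function(d) d$filter_size, 0L)
  expect_true(all(sig >= 70 & sig <= 90))
  expect_true(all(alp >= 11000 & alp <= 13000))
  expect_true(all(fil >= 349 & fil <= 451) && all(fil %% 2 == 1))
  expect_identical(sample_deformation_params(deformation_ranges(), 42),
                   sample_deformation_params(deformation_ranges(), 42))
  expect_error(deformation_ranges(sigma_range = c(5, 2)), "low <= high")
})

test_that("warping: identity, integer shift, hand-computed bilinear, nearest binarity", {
  set.seed(31)
  img <- matrix(runif(30), 5, 6)
  zero <- ddf(matrix(0, 5, 6), matrix(0, 5, 6))
  expect_identical(warp_image(img, zero, "bilinear"), img)
  expect_identical(warp_image(img, zero, "nearest"), img)
  # dx = 1: shifted left by one sample, clamped last column
  sh <- warp_image(img, ddf(matrix(1, 5, 6), matrix(0, 5, 6)))
  expect_equal(sh[, 1:5], img[, 2:6])
  expect_equal(sh[, 6], img[, 6])
  # 2x2 case [[0,1],[2,3]] with dx = 0.5: horizontal neighbour means
  m <- matrix(c(0, 2, 1, 3), 2, 2)
  w <- warp_image(m, ddf(matrix(0.5, 2, 2), matrix(0, 2, 2)))
  expect_equal(w, matrix(c(0.5, 2.5, 1, 3), 2, 2))
  # nearest mode preserves the value set of a binary mask
  mask <- matrix(rbinom(30, 1, 0.5), 5, 6)
  f <- ddf(matrix(runif(30, -1, 1), 5), matrix(runif(30, -1, 1), 5))
  expect_true(all(warp_image(mask, f, "nearest") %in% c(0, 1)))
  expect_error(warp_image(img, ddf(matrix(0, 2, 2), matrix(0, 2, 2))),
               "do not match")
})

test_that("oversized filters raise an error that points at rescaling", {
  expect_error(
    generate_random_ddf(192, 256, deformation_params(70, 1, 351, seed = 1)),
    "rescale_deformation_ranges")
})

test_that("range rescaling scales sigma and F linearly, alpha quadratically", {
  rg <- rescale_deformation_ranges(deformation_ranges(), 0.5)
  expect_equal(rg$sigma_range, c(35, 45))
  expect_equal(rg$alpha_range, c(2750, 3250))
  expect_equal(rg$filter_range, c(175, 225))
})

test_that("augmentation produces the requested variants with recoverable fields", {
  set.seed(32)
  img <- matrix(runif(64 * 64), 64)
  rg <- deformation_ranges(c(4, 6), c(100, 200), c(21, 25))
  recs <- apply_augmentation(img, rg, n_variants = 3, seed = 11)
  expect_length(recs, 3)
  for (r in recs) {
    expect_equal(dim(r$image), dim(img))
    expect_s3_class(r$field, "ddf")
    redo <- generate_random_ddf(64, 64, r$params)
    expect_equal(redo$dx, r$field$dx)
  }
  # zero-intensity range: deformed image equals the input
  still <- apply_augmentation(img, deformation_ranges(c(4, 6), c(0, 0),
                                                      c(21, 25)),
                              n_variants = 1, seed = 3)
  expect_equal(still[[1]]$image, img)
  # displacement-targeted variants land in the requested band
  tg <- apply_augmentation(img, rg, n_variants = 4, seed = 5,
                           target_px = c(2, 4), target_stat = "max")
  for (r in tg) {
    mx <- max(sqrt(r$field$dx^2 + r$field$dy^2))
    expect_gte(mx, 2); expect_lte(mx, 4)
  }
})

test_that("phantom-pair augmentation deforms one modality and its mask together", {
  p <- generate_phantom_pair(small_phantom_config(seed = 6))
  recs <- apply_augmentation(p, rescale_deformation_ranges(
    deformation_ranges(), 0.12), n_variants = 1, seed = 2,
    which = "histology")
  r <- recs[[1]]
  expect_s3_class(r$pair, "phantom_pair")
  # snapshot untouched, histology deformed
  expect_identical(r$pair$snapshot_like, p$snapshot_like)
  expect_false(identical(r$pair$histology_like, p$histology_like))
  # deformed mask stays binary and matches warping the original mask
  expect_true(all(r$deformed_mask %in% c(0, 1)))
  expect_equal(r$deformed_mask,
               warp_image(p$foreground_mask, r$field, "nearest"))
})

test_that("DDF serialisation round-trips (native and float TIFF)", {
  f <- generate_random_ddf(32, 48, deformation_params(4, 80, 17, seed = 8))
  p1 <- tempfile(fileext = ".rds")
  write_ddf(f, p1, params = deformation_params(4, 80, 17, seed = 8))
  back <- read_ddf(p1)
  expect_equal(back$dx, f$dx)
  expect_equal(attr(back, "params")$alpha, 80)
  p2 <- tempfile(fileext = ".tif")
  write_ddf_tiff(f, p2)
  back2 <- read_ddf_tiff(p2)
  # float32 export: absolute quantisation ~ width * 2^-24
  expect_lt(max(abs(back2$dx - f$dx)), 1e-4 * ncol(f$dx))
  expect_lt(max(abs(back2$dy - f$dy)), 1e-4 * ncol(f$dy))
})

test_that("folding diagnostics: smooth small fields do not fold", {
  f <- generate_random_ddf(48, 48, deformation_params(6, 0, 25, seed = 1))
  expect_equal(ddf_jacobian_negatives(f), 0)
})
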