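# Similarity terms, regulariser, composite loss, Dice, Mann-Whitney.

test_that("histogram MI matches hand-computed and brute-force values", {
  # two equally frequent levels, identical images: MI = ln 2
  a <- matrix(c(0, 0, 0.9, 0.9), 2)
  expect_equal(histogram_mi(a, a, 32), log(2))
  # independent binary patterns: joint = product of marginals
  x <- matrix(c(0, 0, 0.9, 0.9), 2)
  y <- matrix(c(0, 0.9, 0, 0.9), 2)
  expect_equal(histogram_mi(x, y, 2), 0)
  # brute-force oracle on small random images, several bin counts
  set.seed(41)
  for (bins in c(2L, 8L, 32L)) {
    a <- matrix(runif(16), 4)
    b <- matrix(runif(16), 4)
    expect_equal(histogram_mi(a, b, bins),
                 oracle_mi_from_counts(oracle_joint_counts(a, b, bins)))
    expect_equal(histogram_mi(a, b, bins), histogram_mi(b, a, bins))
    expect_gte(histogram_mi(a, b, bins), 0)
  }
})

test_that("MI of an image with itself is the binned marginal entropy", {
  set.seed(7)
  a <- matrix(runif(100), 10)
  counts <- tabulate(pmin(floor(a * 16) + 1, 16), 16)
  p <- counts[counts > 0] / 100
  expect_equal(histogram_mi(a, a, 16), -sum(p * log(p)))
})

test_that("MI is invariant to bin-preserving monotone remapping", {
  set.seed(8)
  bins <- 8L
  centers <- (seq_len(bins) - 0.5) / bins
  ia <- sample(bins, 64, replace = TRUE)
  a <- matrix(centers[ia], 8)
  b <- matrix(runif(64), 8)
  # strictly monotone remap of a's levels that keeps each level in its bin
  remap <- centers + 0.02 * seq_len(bins) / bins
  a2 <- matrix(remap[ia], 8)
  expect_equal(histogram_mi(a2, b, bins), histogram_mi(a, b, bins))
})

test_that("joint histogram totals, marginals and errors behave", {
  set.seed(9)
  a <- matrix(runif(30), 5)
  b <- matrix(runif(30), 5)
  jh <- joint_histogram(a, b, 8)
  expect_equal(sum(jh), 30)
  expect_equal(rowSums(jh), tabulate(pmin(floor(a * 8) + 1, 8), 8))
  expect_error(joint_histogram(a, matrix(0, 2, 2), 8), "dimensions")
  expect_error(joint_histogram(a, b, 1), "bin_count")
})

test_that("soft MI orders pairs, hits the hard-binned limit and degenerates to zero", {
  set.seed(10)
  a <- matrix(runif(144), 12)
  shuffled <- matrix(sample(a), 12)
  cfg <- loss_config(bin_count = 16L, soft_bandwidth = 0.02)
  # more shared information -> lower (negated) loss
  expect_lte(soft_mi_loss(a, a, cfg), soft_mi_loss(a, shuffled, cfg))
  # shrinking bandwidth approaches the hard histogram MI
  b <- matrix(runif(144), 12)
  hard <- histogram_mi(a, b, 16)
  err <- vapply(c(0.02, 0.005, 0.001), function(bw)
    abs(-soft_mi_loss(a, b, loss_config(bin_count = 16L,
                                        soft_bandwidth = bw)) - hard), 0)
  expect_lt(err[3], 1e-2)
  expect_true(all(diff(err) < 0))
  # constant image: zero marginal entropy, exactly zero MI
  const <- matrix(0.5, 12, 12)
  expect_equal(as.numeric(soft_mi_loss(const, b, cfg)), 0, tolerance = 1e-12)
})

test_that("MSE matches closed forms", {
  a <- matrix(runif(25), 5)
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a, a + 0.3), 0.09)
  expect_equal(mse_loss(matrix(c(0, 0.5), 1), matrix(c(0.5, 1), 1)), 0.25)
  expect_error(mse_loss(a, matrix(0, 2, 2)), "dimensions")
})

test_that("smoothness penalty: translations score zero, shear 0.5, quadratic scaling", {
  h <- 5; w <- 7
  expect_equal(smoothness_penalty(ddf(matrix(3, h, w), matrix(-11, h, w))), 0)
  shear <- ddf(matrix(rep(0:(w - 1), each = h), h, w), matrix(0, h, w))
  expect_equal(smoothness_penalty(shear), 0.5)
  set.seed(11)
  f <- ddf(matrix(rnorm(h * w), h), matrix(rnorm(h * w), h))
  f2 <- ddf(2 * f$dx, 2 * f$dy)
  expect_equal(smoothness_penalty(f2), 4 * smoothness_penalty(f))
})

test_that("total loss composes similarity and weighted penalty", {
  set.seed(12)
  a <- matrix(runif(64), 8)
  zero <- ddf(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_equal(as.numeric(total_loss(a, a, zero,
                                     loss_config("mse", lambda_smooth = 0))), 0)
  # nonnegative penalty: loss non-decreasing in lambda
  b <- matrix(runif(64), 8)
  f <- ddf(matrix(rnorm(64, 0, 0.4), 8), matrix(rnorm(64, 0, 0.4), 8))
  vals <- vapply(c(0, 0.01, 1), function(l)
    as.numeric(total_loss(a, b, f, loss_config("mse", lambda_smooth = l))), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("total-loss gradient matches central finite differences on 8x8 toys", {
  set.seed(13)
  for (kind in c("mse", "hmi")) {
    cfg <- loss_config(kind, lambda_smooth = 0.05, bin_count = 8L,
                       soft_bandwidth = 0.1)
    fx <- matrix(runif(64), 8); mv <- matrix(runif(64), 8)
    dx <- matrix(rnorm(64, 0, 0.3), 8); dy <- matrix(rnorm(64, 0, 0.3), 8)
    g <- attr(total_loss(fx, mv, ddf(dx, dy), cfg, gradient = TRUE),
              "gradient")
    eps <- 1e-6
    num_dx <- matrix(0, 8, 8); num_dy <- matrix(0, 8, 8)
    for (i in 1:64) {
      d1 <- dx; d2 <- dx; d1[i] <- d1[i] + eps; d2[i] <- d2[i] - eps
      num_dx[i] <- (as.numeric(total_loss(fx, mv, ddf(d1, dy), cfg)) -
                    as.numeric(total_loss(fx, mv, ddf(d2, dy), cfg))) / (2 * eps)
      d1 <- dy; d2 <- dy; d1[i] <- d1[i] + eps; d2[i] <- d2[i] - eps
      num_dy[i] <- (as.numeric(total_loss(fx, mv, ddf(dx, d1), cfg)) -
                    as.numeric(total_loss(fx, mv, ddf(dx, d2), cfg))) / (2 * eps)
    }
    expect_lt(max(abs(num_dx - g$dx)) / max(abs(num_dx)), 1e-4)
    expect_lt(max(abs(num_dy - g$dy)) / max(abs(num_dy)), 1e-4)
  }
})

test_that("Dice covers identity, disjoint, half-overlap and edge cases", {
  m <- matrix(0, 4, 4)
  a <- m; a[1:2, 1] <- 1
  b <- m; b[2:3, 1] <- 1
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, 1 - a), 0)
  expect_equal(dice_score(a, b), 0.5)   # |A| = |B| = 2, overlap 1
  expect_equal(dice_score(a, b), dice_score(b, a))
  expect_equal(dice_score(m, m), 1)     # both empty: vacuous agreement
  expect_error(dice_score(a, m + 0.5), "binary")
})

test_that("Mann-Whitney: no shift, complete separation, exact enumeration oracle", {
  x <- c(1, 2, 3)
  expect_gt(mann_whitney_u(x, x)$p.value, 0.9)
  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(sep$statistic), 0)
  set.seed(14)
  for (rep in 1:8) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- round(runif(nx), 3); y <- round(runif(ny) + 0.2, 3)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p.value, oracle_mann_whitney(x, y), tolerance = 1e-10)
    # independent reference implementation
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                               correct = FALSE))
    expect_equal(unname(got$statistic), unname(ref$statistic))
  }
})

test_that("Mann-Whitney normal approximation handles ties and large samples", {
  set.seed(15)
  x <- sample(1:5, 30, replace = TRUE)
  y <- sample(2:6, 35, replace = TRUE)
  got <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
  expect_equal(mann_whitney_u(rep(1, 5), rep(1, 6))$p.value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})
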