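# Similarity functions (histogram and soft/differentiable mutual
# information, MSE), the smoothness regulariser, the composite
# registration loss, Dice overlap, and the Mann-Whitney U test.

#' Loss configuration
#'
#' @param lsim_kind Similarity term: `"hmi"` (negated histogram-based
#'   mutual information, used unsupervised) or `"mse"` (mean squared
#'   error, used supervised).
#' @param lambda_smooth Nonnegative weight of the smoothness regulariser.
#'   Default 0.01.
#' @param bin_count Number of intensity bins for MI. Default 32, a standard
#'   choice for 8-bit-derived intensities at 256 x 192 resolution.
#' @param soft_bandwidth Standard deviation of the Gaussian (Parzen)
#'   soft-binning window that makes MI differentiable; in intensity units.
#'   Default 0.02 (roughly two thirds of a bin width at 32 bins).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lsim_kind = c("hmi", "mse"), lambda_smooth = 0.01,
                        bin_count = 32L, soft_bandwidth = 0.02) {
  lsim_kind <- match.arg(lsim_kind)
  if (bin_count < 2) stop2("bin_count must be >= 2")
  if (lambda_smooth < 0) stop2("lambda_smooth must be nonnegative")
  if (soft_bandwidth <= 0) stop2("soft_bandwidth must be positive")
  structure(list(lsim_kind = lsim_kind, lambda_smooth = lambda_smooth,
                 bin_count = as.integer(bin_count),
                 soft_bandwidth = soft_bandwidth),
            class = "loss_config")
}

#' Joint intensity histogram of two images
#'
#' Hard-binned joint histogram over \[0, 1\] with `bin_count` equal-width
#' bins per image (a value of exactly 1 falls in the last bin).
#'
#' @param a,b Numeric grayscale matrices in \[0, 1\], equal dimensions.
#' @param bin_count Number of bins per axis (>= 2).
#' @return A `bin_count` x `bin_count` count matrix whose total equals the
#'   number of pixels.
#' @export
joint_histogram <- function(a, b, bin_count = 32L) {
  if (!all(dim(a) == dim(b))) stop2("images must have identical dimensions")
  if (bin_count < 2) stop2("bin_count must be >= 2")
  assert_image01(a); assert_image01(b)
  ia <- pmin(floor(as.vector(a) * bin_count), bin_count - 1L) + 1L
  ib <- pmin(floor(as.vector(b) * bin_count), bin_count - 1L) + 1L
  matrix(tabulate(ia + bin_count * (ib - 1L), nbins = bin_count^2),
         bin_count, bin_count)
}

#' Histogram-based mutual information (HMI)
#'
#' `HMI(F, M) = sum_ij p(i,j) ln( p(i,j) / (p(i) p(j)) )`, where `p(i,j)`
#' is the joint probability of binned intensities and `p(i)`, `p(j)` the
#' marginals. Terms with `p(i,j) = 0` contribute zero. Natural logarithm,
#' so the result is in nats; always `>= 0` and symmetric in its arguments.
#'
#' @inheritParams joint_histogram
#' @return Mutual information in nats.
#' @examples
#' a <- matrix(c(0, 0, 0.9, 0.9), 2)
#' histogram_mi(a, a, 32)  # = ln 2, the entropy of two equal-mass levels
#' @export
histogram_mi <- function(a, b, bin_count = 32L) {
  counts <- joint_histogram(a, b, bin_count)
  p <- counts / sum(counts)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

# Gaussian (Parzen) soft-binning weights: n x bins, rows sum to 1.
parzen_weights <- function(v, bins, bw) cpp_parzen_weights(v, bins, bw)

# Soft mutual information with analytic gradient w.r.t. the pixels of b.
soft_mi <- function(a, b, bins, bw, grad = FALSE) {
  va <- as.vector(a); vb <- as.vector(b)
  n <- length(va)
  wa <- parzen_weights(va, bins, bw)
  wb <- parzen_weights(vb, bins, bw)
  p <- crossprod(wa, wb) / n
  pa <- rowSums(p); pb <- colSums(p)
  eps <- 1e-300
  logratio <- log(pmax(p, eps)) - log(pmax(outer(pa, pb), eps))
  mi <- sum(p * logratio)
  if (!grad) return(list(value = mi))
  centers <- (seq_len(bins) - 0.5) / bins
  g <- wa %*% (logratio - 1) / n          # dMI/dWb, n x bins
  aw <- g * wb
  m <- (as.vector(wb %*% centers) - vb) / bw^2
  dv <- (as.vector(aw %*% centers) - vb * rowSums(aw)) / bw^2 -
    m * rowSums(aw)
  list(value = mi, grad_b = matrix(dv, nrow(b), ncol(b)))
}

#' Differentiable mutual-information loss (Parzen soft binning)
#'
#' Mutual information computed with Gaussian soft-binning so that
#' gradients flow to pixel values, returned negated for minimisation
#' (training maximises MI). As `soft_bandwidth -> 0` the value approaches
#' `-histogram_mi(a, b, bin_count)`.
#'
#' @param a,b Numeric grayscale matrices in \[0, 1\], equal dimensions.
#' @param config A [loss_config()]; `bin_count` and `soft_bandwidth` are
#'   used.
#' @return Negated soft MI (scalar). With `attr(, "gradient")`: the
#'   gradient with respect to the pixels of `b` when `gradient = TRUE`.
#' @param gradient If `TRUE`, attach the analytic gradient w.r.t. `b`.
#' @export
soft_mi_loss <- function(a, b, config = loss_config(), gradient = FALSE) {
  if (!all(dim(a) == dim(b))) stop2("images must have identical dimensions")
  r <- soft_mi(a, b, config$bin_count, config$soft_bandwidth, grad = gradient)
  out <- -r$value
  if (gradient) attr(out, "gradient") <- -r$grad_b
  out
}

#' Mean squared error between a label image and a prediction
#'
#' `MSE(gamma, pred) = mean_i (gamma_i - pred_i)^2` over all pixels.
#'
#' @param gamma Ground-truth (label) image.
#' @param predicted Predicted (warped) image of identical dimensions.
#' @return Nonnegative scalar.
#' @export
mse_loss <- function(gamma, predicted) {
  if (!all(dim(gamma) == dim(predicted)))
    stop2("images must have identical dimensions")
  mean((gamma - predicted)^2)
}

#' Smoothness penalty on a displacement field
#'
#' Mean squared forward-difference spatial gradient of the two displacement
#' components (the diffusion regulariser):
#' `0.5 * sum_{c in {dx, dy}} [ mean((D_x c)^2) + mean((D_y c)^2) ]`,
#' with each mean over the valid forward differences. Zero exactly for
#' spatially constant fields (translations); quadratic, so doubling the
#' field quadruples the penalty. A unit shear (`dx = x`) scores 0.5.
#'
#' @param field A [ddf()] object.
#' @param gradient If `TRUE`, attach `attr(, "gradient")`, a list with the
#'   penalty gradient w.r.t. `dx` and `dy`.
#' @return Nonnegative scalar.
#' @export
smoothness_penalty <- function(field, gradient = FALSE) {
  stopifnot(inherits(field, "ddf"))
  h <- field$height; w <- field$width
  comp <- function(c) {
    val <- 0
    gr <- matrix(0, h, w)
    if (w > 1) {
      t <- c[, -1, drop = FALSE] - c[, -w, drop = FALSE]
      val <- val + mean(t^2)
      s <- t / length(t)
      gr[, -1] <- gr[, -1] + s
      gr[, -w] <- gr[, -w] - s
    }
    if (h > 1) {
      t <- c[-1, , drop = FALSE] - c[-h, , drop = FALSE]
      val <- val + mean(t^2)
      s <- t / length(t)
      gr[-1, ] <- gr[-1, ] + s
      gr[-h, ] <- gr[-h, ] - s
    }
    list(val = val, gr = gr)
  }
  cx <- comp(field$dx); cy <- comp(field$dy)
  out <- 0.5 * (cx$val + cy$val)
  if (gradient) attr(out, "gradient") <- list(dx = cx$gr, dy = cy$gr)
  out
}

#' Composite registration loss
#'
#' Warps the moving image by the field, applies the configured similarity
#' term to (fixed, warped) and adds `lambda_smooth` times the smoothness
#' penalty: `L = Lsim(F, M(phi)) + lambda * Lsmooth(phi)`.
#'
#' @param fixed,moving Grayscale matrices in \[0, 1\], equal dimensions.
#' @param field A [ddf()] matching the image dimensions.
#' @param config A [loss_config()].
#' @param gradient If `TRUE`, attach `attr(, "gradient")`: a list with the
#'   loss gradient w.r.t. the field components `dx` and `dy`, and the
#'   warped image under `attr(, "warped")`.
#' @return Scalar loss (negated soft MI, or MSE, plus the weighted
#'   penalty).
#' @export
total_loss <- function(fixed, moving, field, config = loss_config(),
                       gradient = FALSE) {
  stopifnot(inherits(field, "ddf"), inherits(config, "loss_config"))
  if (!all(dim(fixed) == dim(moving)))
    stop2("fixed and moving must have identical dimensions")
  if (nrow(fixed) != field$height || ncol(fixed) != field$width)
    stop2("field dimensions do not match the images")
  warped <- warp_image(moving, field, "bilinear")
  if (config$lsim_kind == "hmi") {
    s <- soft_mi(fixed, warped, config$bin_count, config$soft_bandwidth,
                 grad = gradient)
    sim <- -s$value
    dsim <- if (gradient) -s$grad_b else NULL
  } else {
    sim <- mse_loss(fixed, warped)
    dsim <- if (gradient) 2 * (warped - fixed) / length(fixed) else NULL
  }
  sp <- smoothness_penalty(field, gradient = gradient)
  out <- sim + config$lambda_smooth * as.numeric(sp)
  if (gradient) {
    arr <- moving; dim(arr) <- c(dim(moving), 1L)
    darr <- dsim; dim(darr) <- c(dim(dsim), 1L)
    wb <- cpp_warp_backward(arr, field$dx, field$dy, darr)
    spg <- attr(sp, "gradient")
    attr(out, "gradient") <- list(
      dx = wb$ddx + config$lambda_smooth * spg$dx,
      dy = wb$ddy + config$lambda_smooth * spg$dy)
    attr(out, "warped") <- warped
  }
  out
}

#' Dice overlap between two binary masks
#'
#' `Dice(A, B) = 2 |A intersect B| / (|A| + |B|)`, in \[0, 1\]. Defined as
#' 1 when both masks are empty (vacuous perfect agreement).
#'
#' @param a,b Binary (\{0, 1\} or logical) matrices of equal dimensions.
#' @return Scalar in \[0, 1\].
#' @export
dice_score <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop2("masks must have identical dimensions")
  av <- as.vector(a); bv <- as.vector(b)
  if (!all(av %in% c(0, 1)) || !all(bv %in% c(0, 1)))
    stop2("masks must be binary (0/1)")
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1)
  2 * sum(av * bv) / (sa + sb)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum U statistic with average ranks for ties. The p-value is exact
#' for small samples — from the closed-form null distribution of U when
#' there are no ties (both n at most 20), or by exhaustive enumeration of
#' rank assignments when ties are present and the pooled sample has at
#' most 18 observations; larger problems use a normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y Nonempty numeric vectors.
#' @return An object of class `htest` with the U statistic for `x` and the
#'   two-sided p-value.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop2("both samples must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && nx <= 20 && ny <= 20) {
    p <- if (u > mu) 2 * (1 - pwilcox(u - 1, nx, ny)) else
      2 * pwilcox(u, nx, ny)
    p <- min(p, 1)
    method <- "Mann-Whitney U test (exact)"
  } else if (has_ties && n <= 18) {
    # exact two-sided p under ties: enumerate all assignments of the
    # pooled (average) ranks to the x positions
    combs <- utils::combn(n, nx)
    us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "Mann-Whitney U test (exact, tie enumeration)"
  } else {
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "Mann-Whitney U test (normal approximation)"
  }
  structure(list(statistic = c(U = u), p.value = p, method = method,
                 data.name = paste(deparse1(substitute(x)), "and",
                                   deparse1(substitute(y))),
                 alternative = "two.sided"),
            class = "htest")
}
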