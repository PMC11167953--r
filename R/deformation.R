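# Random smooth dense displacement fields (elastic augmentation) and
# image warping under a field (the spatial-transformer resampler).

#' Dense displacement field
#'
#' A dense displacement field (DDF) stores, for every output pixel, a 2-D
#' offset `(dx, dy)` in pixel units. The convention is backward warping:
#' output pixel `(x, y)` samples the input image at `(x + dx, y + dy)`, as
#' in standard spatial-transformer practice.
#'
#' @param dx,dy Numeric matrices of identical dimensions holding the
#'   per-pixel offsets along the x (column) and y (row) axes, in pixels.
#' @return An object of class `ddf` with elements `dx`, `dy`, `height`,
#'   `width`.
#' @examples
#' f <- ddf(matrix(1, 4, 4), matrix(0, 4, 4))
#' f$height
#' @export
ddf <- function(dx, dy) {
  if (!is.matrix(dx) || !is.matrix(dy) || !all(dim(dx) == dim(dy)))
    stop2("dx and dy must be matrices with identical dimensions")
  if (any(!is.finite(dx)) || any(!is.finite(dy)))
    stop2("displacement fields must be finite")
  structure(list(dx = dx, dy = dy, height = nrow(dx), width = ncol(dx)),
            class = "ddf")
}

#' @export
print.ddf <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("Dense displacement field %d x %d px\n", x$height, x$width))
  cat(sprintf("  |displacement|: mean %.3f, max %.3f px\n",
              mean(mag), max(mag)))
  invisible(x)
}

#' Elastic deformation parameters
#'
#' One synthetic elastic deformation is governed by the triple
#' (sigma, alpha, F): per-pixel i.i.d. uniform(-1, 1) noise is smoothed with
#' a Gaussian filter of standard deviation `sigma` (the elasticity
#' coefficient) and kernel side `filter_size`, then scaled by `alpha` to
#' control deformation intensity.
#'
#' @param sigma Gaussian standard deviation in pixels; must be positive.
#' @param alpha Nonnegative scale factor applied to the smoothed field.
#' @param filter_size Gaussian kernel side length in pixels; rounded to the
#'   nearest odd integer.
#' @param seed Integer seed making the deformation reproducible.
#' @return An object of class `deformation_params`.
#' @export
deformation_params <- function(sigma, alpha, filter_size, seed = 1L) {
  if (!is.numeric(sigma) || sigma <= 0) stop2("sigma must be positive")
  if (!is.numeric(alpha) || alpha < 0) stop2("alpha must be nonnegative")
  f <- round(filter_size)
  if (f %% 2 == 0) f <- f + (if (filter_size >= f) 1L else -1L)
  f <- as.integer(max(f, 1L))
  structure(list(sigma = sigma, alpha = alpha, filter_size = f,
                 seed = as.integer(seed)),
            class = "deformation_params")
}

#' Deformation intensity ranges
#'
#' Ranges from which (sigma, alpha, F) are drawn uniformly for each
#' augmentation variant. The defaults, sigma in \[70, 90\], alpha in
#' \[11000, 13000\] and F in \[350, 450\], are meant for images at native
#' camera/scan resolution (around 1000 px wide); use
#' [rescale_deformation_ranges()] when deforming at other resolutions.
#'
#' @param sigma_range,alpha_range,filter_range Numeric `c(low, high)` with
#'   `low <= high`.
#' @return An object of class `deformation_ranges`.
#' @export
deformation_ranges <- function(sigma_range = c(70, 90),
                               alpha_range = c(11000, 13000),
                               filter_range = c(350, 450)) {
  chk <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop2("%s must be c(low, high) with low <= high", nm)
    r
  }
  structure(list(sigma_range = chk(sigma_range, "sigma_range"),
                 alpha_range = chk(alpha_range, "alpha_range"),
                 filter_range = chk(filter_range, "filter_range")),
            class = "deformation_ranges")
}

#' Rescale deformation ranges to another image resolution
#'
#' When an image is resized by a linear factor `f`, obtaining the same
#' deformation relative to the image requires `sigma -> f * sigma`,
#' `F -> f * F`, and `alpha -> f^2 * alpha`: the unit-sum Gaussian kernel's
#' amplitude scales as `1/f`, so displacement magnitude scales with
#' `alpha * f^2 / f = alpha_new / (alpha * f)` being constant relative to
#' image size only when alpha picks up the extra factor of `f`.
#'
#' @param ranges A [deformation_ranges()] object.
#' @param factor Linear resize factor (new size / old size).
#' @return A rescaled `deformation_ranges` object.
#' @export
rescale_deformation_ranges <- function(ranges, factor) {
  stopifnot(inherits(ranges, "deformation_ranges"), factor > 0)
  deformation_ranges(sigma_range = ranges$sigma_range * factor,
                     alpha_range = ranges$alpha_range * factor^2,
                     filter_range = pmax(ranges$filter_range * factor, 1))
}

#' Draw deformation parameters from intensity ranges
#'
#' @param ranges A [deformation_ranges()] object.
#' @param rng_seed Integer seed; the same seed always yields the same
#'   (sigma, alpha, F) triple.
#' @return A [deformation_params()] object (filter size rounded to the
#'   nearest odd integer).
#' @export
sample_deformation_params <- function(ranges, rng_seed = 1L) {
  stopifnot(inherits(ranges, "deformation_ranges"))
  draws <- with_substream(rng_seed, "params", 0L, {
    c(runif(1, ranges$sigma_range[1], ranges$sigma_range[2]),
      runif(1, ranges$alpha_range[1], ranges$alpha_range[2]),
      runif(1, ranges$filter_range[1], ranges$filter_range[2]))
  })
  deformation_params(sigma = draws[1], alpha = draws[2],
                     filter_size = draws[3], seed = rng_seed)
}

#' Generate a random smooth dense displacement field
#'
#' Draws i.i.d. uniform(-1, 1) noise per pixel for both displacement
#' components, convolves each with a unit-sum Gaussian kernel (side
#' `filter_size`, standard deviation `sigma`, reflective boundary), and
#' scales the result by `alpha`. Deterministic in `params$seed`; the two
#' components use independent substreams.
#'
#' @param height,width Field dimensions in pixels.
#' @param params A [deformation_params()] object.
#' @param max_filter_frac Maximum allowed ratio of `filter_size` to the
#'   smaller image dimension before an error suggests rescaling the
#'   parameters (see [rescale_deformation_ranges()]).
#' @return A [ddf()] object.
#' @examples
#' f <- generate_random_ddf(64, 64, deformation_params(8, 100, 33, seed = 1))
#' max(abs(f$dx))
#' @export
generate_random_ddf <- function(height, width, params,
                                max_filter_frac = 1) {
  stopifnot(inherits(params, "deformation_params"))
  if (height < 1 || width < 1) stop2("field dimensions must be positive")
  if (params$filter_size > max_filter_frac * min(height, width))
    stop2(paste("filter_size %d exceeds %g x the smaller image dimension",
                "(%d px); rescale (sigma, alpha, F) to this resolution",
                "with rescale_deformation_ranges()"),
          params$filter_size, max_filter_frac, min(height, width))
  ux <- with_substream(params$seed, "field-x", 0L,
                       matrix(runif(height * width, -1, 1), height, width))
  uy <- with_substream(params$seed, "field-y", 0L,
                       matrix(runif(height * width, -1, 1), height, width))
  dx <- params$alpha * cpp_sepgauss(ux, params$sigma, params$filter_size)
  dy <- params$alpha * cpp_sepgauss(uy, params$sigma, params$filter_size)
  ddf(dx, dy)
}

#' Warp an image with a dense displacement field
#'
#' Backward warping: output pixel `(x, y)` samples the input at
#' `(x + dx, y + dy)` with the chosen interpolation; out-of-bounds sampling
#' clamps to the border. Multi-channel images are warped channel-wise with
#' the same field.
#'
#' @param image Numeric matrix (grayscale) or H x W x C array, any range.
#' @param field A [ddf()] with the same spatial dimensions as `image`.
#' @param mode `"bilinear"` (intensities) or `"nearest"` (masks/labels).
#' @return Warped image with the dimensions of `image`.
#' @examples
#' img <- matrix(runif(16), 4, 4)
#' identical(warp_image(img, ddf(matrix(0, 4, 4), matrix(0, 4, 4))), img)
#' @export
warp_image <- function(image, field, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "ddf"))
  d <- dim(image)
  if (is.null(d) || d[1] != field$height || d[2] != field$width)
    stop2("image dimensions (%s) do not match field dimensions (%d x %d)",
          paste(d, collapse = " x "), field$height, field$width)
  arr <- if (length(d) == 2L) {
    a <- image; dim(a) <- c(d, 1L); a
  } else image
  out <- if (mode == "bilinear") cpp_warp_bilinear(arr, field$dx, field$dy)
         else cpp_warp_nearest(arr, field$dx, field$dy)
  if (length(d) == 2L) dim(out) <- d
  out
}

#' Count folded pixels in a displacement field
#'
#' Number of pixels where the Jacobian determinant of the mapping
#' `x -> x + u(x)` (forward differences) is negative, i.e. where the field
#' folds space. Folding is reported, not prevented.
#'
#' @param field A [ddf()] object.
#' @return Integer count of negative-Jacobian pixels.
#' @export
ddf_jacobian_negatives <- function(field) {
  stopifnot(inherits(field, "ddf"))
  h <- field$height; w <- field$width
  dxx <- 1 + (field$dx[, -1, drop = FALSE] - field$dx[, -w, drop = FALSE])
  dyx <- (field$dy[, -1, drop = FALSE] - field$dy[, -w, drop = FALSE])
  dxy <- (field$dx[-1, , drop = FALSE] - field$dx[-h, , drop = FALSE])
  dyy <- 1 + (field$dy[-1, , drop = FALSE] - field$dy[-h, , drop = FALSE])
  jac <- dxx[-h, ] * dyy[, -w] - dyx[-h, ] * dxy[, -w]
  sum(jac < 0)
}

#' Elastic-deformation augmentation
#'
#' Generates `n_variants` independently parameterised elastic deformations
#' of an image (or of one modality of a phantom pair), recording the
#' sampled parameters and the exact field for each variant so ground-truth
#' warps stay recoverable.
#'
#' @param x A numeric image (matrix or H x W x C array) or a
#'   [generate_phantom_pair()] object.
#' @param ranges A [deformation_ranges()] object (ignored when
#'   `target_max_px` is given, except for sigma and filter size).
#' @param n_variants Number of deformed variants to generate.
#' @param seed Root seed; variant `i` uses substream `(seed, "variant", i)`.
#' @param which For phantom pairs: which modality to deform
#'   (`"histology"` or `"snapshot"`). Masks are deformed with the same
#'   field using nearest-neighbour interpolation.
#' @param target_px Optional `c(low, high)`: instead of drawing alpha from
#'   `ranges`, each variant's field is rescaled so the chosen displacement
#'   statistic equals a uniform draw from this interval (in pixels).
#'   Useful for controlled-recovery experiments where deformation strength
#'   must be exact by construction.
#' @param target_stat Statistic controlled by `target_px`: `"mean"`
#'   (default; mean displacement magnitude over the field) or `"max"`.
#' @return A list of length `n_variants`; each element has `image` (or
#'   `pair` for phantom input), `field` (a [ddf()]) and `params`.
#' @export
apply_augmentation <- function(x, ranges = deformation_ranges(),
                               n_variants = 5L, seed = 1L,
                               which = c("histology", "snapshot"),
                               target_px = NULL,
                               target_stat = c("mean", "max")) {
  which <- match.arg(which)
  target_stat <- match.arg(target_stat)
  if (n_variants < 1) stop2("n_variants must be >= 1")
  is_pair <- inherits(x, "phantom_pair")
  img <- if (is_pair) {
    if (which == "histology") x$histology_like else x$snapshot_like
  } else x
  d <- dim(img)
  h <- d[1]; w <- d[2]
  lapply(seq_len(n_variants), function(i) {
    vseed <- substream_seed(seed, "variant", i)
    params <- sample_deformation_params(ranges, rng_seed = vseed)
    if (!is.null(target_px)) {
      target <- with_substream(vseed, "target", 0L,
                               runif(1, target_px[1], target_px[2]))
      p1 <- deformation_params(params$sigma, 1, params$filter_size,
                               seed = vseed)
      unit <- generate_random_ddf(h, w, p1)
      mag <- sqrt(unit$dx^2 + unit$dy^2)
      m <- if (target_stat == "max") max(mag) else mean(mag)
      alpha <- if (m > 0) target / m else 0
      params <- deformation_params(params$sigma, alpha, params$filter_size,
                                   seed = vseed)
      field <- ddf(alpha * unit$dx, alpha * unit$dy)
    } else {
      field <- generate_random_ddf(h, w, params)
    }
    if (is_pair) {
      out <- x
      if (which == "histology")
        out$histology_like <- warp_image(x$histology_like, field, "bilinear")
      else
        out$snapshot_like <- warp_image(x$snapshot_like, field, "bilinear")
      # the pair's stored masks keep describing the undeformed shared
      # geometry; the deformed modality's own mask travels with the record
      list(pair = out, field = field, params = params,
           deformed_mask = warp_image(x$foreground_mask, field, "nearest"),
           deformed_structures = warp_image(x$structure_mask, field,
                                            "nearest"))
    } else {
      list(image = warp_image(img, field, "bilinear"),
           field = field, params = params)
    }
  })
}

#' Save / load a dense displacement field
#'
#' `write_ddf()` stores dx, dy and a metadata record in R's native
#' serialisation (lossless). `write_ddf_tiff()` exports a 2-band 32-bit
#' float TIFF (band 1 = dx, band 2 = dy); since the TIFF float range is
#' \[0, 1\], displacements are stored as `v / (2 * width) + 0.5` — the
#' scale is recovered from the raster width on read, and the quantisation
#' is single precision (absolute error around `1e-4` px for typical image
#' sizes). Displacements beyond one image width are not representable and
#' raise an error.
#'
#' @param field A [ddf()] object.
#' @param path Output file path.
#' @param params Optional [deformation_params()] stored alongside.
#' @return `read_ddf()` returns the [ddf()] (with `params` attribute when
#'   present); the writers return `path` invisibly.
#' @export
write_ddf <- function(field, path, params = NULL) {
  stopifnot(inherits(field, "ddf"))
  saveRDS(list(dx = field$dx, dy = field$dy,
               meta = list(height = field$height, width = field$width,
                           params = params)),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_ddf
#' @export
read_ddf <- function(path) {
  obj <- readRDS(path)
  f <- ddf(obj$dx, obj$dy)
  if (!is.null(obj$meta$params)) attr(f, "params") <- obj$meta$params
  f
}

#' @rdname write_ddf
#' @export
write_ddf_tiff <- function(field, path) {
  stopifnot(inherits(field, "ddf"))
  s <- 2 * field$width
  if (max(abs(field$dx), abs(field$dy)) >= field$width)
    stop2("displacements exceed one image width; use write_ddf() instead")
  arr <- array(c(field$dx / s + 0.5, field$dy / s + 0.5),
               dim = c(field$height, field$width, 2L))
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_ddf
#' @export
read_ddf_tiff <- function(path) {
  # libtiff flags the two non-colour bands as ExtraSamples; harmless here
  arr <- suppressWarnings(tiff::readTIFF(path, as.is = FALSE))
  s <- 2 * ncol(arr[, , 1])
  ddf((arr[, , 1] - 0.5) * s, (arr[, , 2] - 0.5) * s)
}
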