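# Modality-specific grayscale conversion, resizing to the model grid,
# foreground-mask extraction, and raster IO.
#
# All images are plain numeric arrays, dim (H, W) or (H, W, C), values in
# [0, 1]; 8-bit files are divided by 255 on load and all internal math is
# floating point.

#' Read an RGB or grayscale raster image
#'
#' Reads PNG, TIFF or JPEG into an H x W (grayscale) matrix or H x W x 3
#' array with values in \[0, 1\]. An alpha channel, if present, is dropped.
#'
#' @param path File path.
#' @return Numeric matrix or H x W x 3 array in \[0, 1\].
#' @export
read_image <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  # EBImage stores (x, y[, c]); transpose to (row = y, col = x)
  img <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2, 1, 3))
  if (length(dim(img)) == 3L && dim(img)[3] >= 4L)
    img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) dim(img) <- dim(img)[1:2]
  pmin(pmax(img, 0), 1)
}

#' Write an image as 8-bit PNG (round-half-up quantisation) or float TIFF
#'
#' @param image Numeric matrix or H x W x C array in \[0, 1\].
#' @param path Output path; the writer is chosen by extension
#'   (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_image01(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    q <- floor(image * 255 + 0.5) / 255
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 32L)
  } else stop2("unsupported image extension '%s'", ext)
  invisible(path)
}

#' Histology grayscale conversion (weighted colour average)
#'
#' Converts an RGB histology image to grayscale with the weighted average
#' `0.299 R + 0.587 G + 0.114 B`, emphasising structures stained in the
#' green-absorbing range.
#'
#' @param image H x W x 3 numeric array with values in \[0, 1\].
#' @return H x W grayscale matrix in \[0, 1\].
#' @examples
#' px <- array(c(0, 1, 0), dim = c(1, 1, 3))
#' histology_to_gray(px)  # 0.587
#' @export
histology_to_gray <- function(image) {
  assert_image01(image, "RGB image")
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop2("expected an H x W x 3 RGB array")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Snapshot grayscale conversion (HSV saturation)
#'
#' Converts an RGB specimen-snapshot image to grayscale using saturation
#' values only: `S = (max - min) / max` over the colour channels, with
#' `S = 0` where `max = 0`. Saturation suppresses the achromatic background
#' and brings the snapshot's intensity statistics closer to the histology
#' grayscale.
#'
#' @param image H x W x 3 numeric array with values in \[0, 1\].
#' @return H x W grayscale matrix in \[0, 1\].
#' @examples
#' px <- array(c(0.5, 0.25, 0.25), dim = c(1, 1, 3))
#' snapshot_to_gray(px)  # 0.5
#' @export
snapshot_to_gray <- function(image) {
  assert_image01(image, "RGB image")
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop2("expected an H x W x 3 RGB array")
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  matrix(s, nrow = dim(image)[1])
}

#' Resize an image
#'
#' Downscaling uses coverage-weighted area averaging (anti-aliased; exact
#' block means for integer factors); upscaling uses bilinear interpolation;
#' `mode = "nearest"` is for masks and label images. Mixed up/down
#' directions fall back to bilinear.
#'
#' @param image Numeric matrix or H x W x C array.
#' @param height,width Target dimensions in pixels.
#' @param mode `"auto"` (area for downscale, bilinear otherwise),
#'   `"bilinear"`, `"area"` or `"nearest"`.
#' @return Resized image with the same number of channels.
#' @export
resize_image <- function(image, height, width,
                         mode = c("auto", "bilinear", "area", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (is.null(d)) stop2("image must be a matrix or array")
  if (height < 1 || width < 1) stop2("target dimensions must be positive")
  if (mode == "auto")
    mode <- if (height <= d[1] && width <= d[2]) "area" else "bilinear"
  one <- function(m) {
    switch(mode,
      area = cpp_resize_area(m, as.integer(height), as.integer(width)),
      bilinear = cpp_resize_bilinear(m, as.integer(height), as.integer(width)),
      nearest = {
        ri <- pmin(pmax(floor((seq_len(height) - 0.5) * d[1] / height) + 1,
                        1), d[1])
        ci <- pmin(pmax(floor((seq_len(width) - 0.5) * d[2] / width) + 1,
                        1), d[2])
        m[ri, ci, drop = FALSE]
      })
  }
  if (length(d) == 2L) return(one(image))
  out <- array(0, dim = c(height, width, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- one(image[, , c])
  out
}

#' Resize a grayscale image to the model input resolution
#'
#' The registration network operates on 256 (wide) x 192 (high) grayscale
#' images; this resamples any input to that grid (idempotent when the
#' input already has the target size).
#'
#' @param image Numeric grayscale matrix in \[0, 1\].
#' @param mode Passed to [resize_image()].
#' @return A 192 x 256 matrix in \[0, 1\].
#' @export
resize_to_model <- function(image, mode = "auto") {
  if (nrow(image) == 192L && ncol(image) == 256L && mode != "nearest")
    return(image)
  out <- resize_image(image, 192L, 256L, mode = mode)
  pmin(pmax(out, 0), 1)
}

#' Foreground (tissue) mask of a grayscale image
#'
#' Binarises with Otsu's threshold, picks the polarity whose class occupies
#' less of the image border (tissue rarely touches the frame), keeps the
#' largest connected component and fills its holes. Used to compute Dice
#' overlap, which is defined between two binary images.
#'
#' @param image Numeric grayscale matrix in \[0, 1\].
#' @return A \{0, 1\} numeric matrix. A constant (degenerate) input returns
#'   an all-ones mask with a warning.
#' @export
foreground_mask <- function(image) {
  assert_image01(image, "grayscale image")
  if (max(image) - min(image) < 1e-12) {
    warning("constant image: returning an all-ones foreground mask")
    return(matrix(1, nrow(image), ncol(image)))
  }
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  hi <- image > thr
  border <- function(m) {
    mean(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
  }
  fg <- if (border(hi) <= border(!hi)) hi else !hi
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  if (max(lab) >= 1) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    fg <- lab == which.max(sizes)
  }
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1)))
  matrix(as.numeric(filled > 0), nrow(image), ncol(image))
}
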