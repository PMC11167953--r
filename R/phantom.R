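# Paired multi-modal phantoms: two renderings of the same tissue-like
# geometry (a smooth foreground blob with internal structures) that differ
# in colour distribution, contrast and texture the way an H&E section and
# a specimen snapshot do, optionally with tear/hole artifacts in the
# histology-like rendering. Every other module is testable on phantoms
# without access to clinical data.

# Fixed rendering palettes (RGB in [0,1]); constants so regression tests
# are stable. Chosen so that (a) the histology weighted-average grayscale
# and the snapshot saturation grayscale both separate background / tissue /
# structure well, and (b) the two renderings differ clearly per channel.
.palette_histology <- list(background = c(0.96, 0.94, 0.96),
                           tissue     = c(0.90, 0.55, 0.70),
                           structure  = c(0.38, 0.18, 0.50))
.palette_snapshot  <- list(background = c(0.94, 0.94, 0.95),
                           tissue     = c(0.90, 0.72, 0.58),
                           structure  = c(0.80, 0.68, 0.25))

#' Phantom generator configuration
#'
#' @param image_height,image_width Raster dimensions in pixels (>= 32).
#' @param n_structures Number of internal blob structures inside the
#'   tissue foreground.
#' @param artifact_rate Probability (per pair) that the histology-like
#'   rendering receives a tear or hole artifact, in \[0, 1\].
#' @param seed Integer root seed; identical configuration implies
#'   bit-identical output.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 384L, image_width = 512L,
                           n_structures = 5L, artifact_rate = 0.3,
                           seed = 1L) {
  if (image_height < 32 || image_width < 32)
    stop2("image dimensions must be at least 32 px")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop2("artifact_rate must be in [0, 1]")
  if (n_structures < 0) stop2("n_structures must be nonnegative")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_structures = as.integer(n_structures),
                 artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Sum of Gaussian bumps on the pixel grid.
.bump_field <- function(h, w, cx, cy, sg) {
  f <- matrix(0, h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  for (k in seq_along(cx))
    f <- f + exp(-((X - cx[k])^2 + (Y - cy[k])^2) / (2 * sg[k]^2))
  f
}

.largest_component_filled <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (max(lab) >= 1) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    mask <- lab == which.max(sizes)
  }
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))
  matrix(as.numeric(filled > 0), nrow(mask), ncol(mask))
}

.render_modality <- function(fg, smask, palette) {
  h <- nrow(fg); w <- ncol(fg)
  img <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) {
    ch <- matrix(palette$background[c], h, w)
    ch[fg > 0] <- palette$tissue[c]
    ch[smask > 0] <- palette$structure[c]
    img[, , c] <- ch
  }
  img
}

.paint_mask <- function(img, where, colour) {
  for (c in 1:3) {
    ch <- img[, , c]
    ch[where] <- colour[c]
    img[, , c] <- ch
  }
  img
}

#' Generate one paired multi-modal phantom
#'
#' Builds a smooth organic foreground blob (thresholded sum of randomly
#' placed Gaussian bumps), places `n_structures` elliptical internal
#' structures, and renders the shared geometry twice: a histology-like
#' image (pink/purple palette, fine-grain texture) and a snapshot-like
#' image (flesh/yellow palette, coarse low-frequency shading). With
#' probability `artifact_rate` the histology-like rendering receives a
#' tear (thin background-coloured crack) or a hole; artifacts change the
#' rendering only, never the stored geometry masks.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_pair`: a list with `histology_like`
#'   and `snapshot_like` (H x W x 3 arrays in \[0, 1\]), `foreground_mask`
#'   (\{0, 1\} matrix, shared by both renderings), `structure_mask` (label
#'   matrix 0..n_structures) and the `config`.
#' @examples
#' p <- generate_phantom_pair(phantom_config(64, 64, n_structures = 2,
#'                                           artifact_rate = 0, seed = 7))
#' dim(p$histology_like)
#' @export
generate_phantom_pair <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$image_height; w <- config$image_width
  mind <- min(h, w)
  seed <- config$seed

  geo <- with_substream(seed, "geometry", 0L, {
    k <- 6L
    list(cx = runif(k, 0.32 * w, 0.68 * w),
         cy = runif(k, 0.32 * h, 0.68 * h),
         sg = runif(k, 0.12, 0.20) * mind)
  })
  field <- .bump_field(h, w, geo$cx, geo$cy, geo$sg)
  fg <- .largest_component_filled(field > 0.5 * max(field))
  interior <- field > 0.65 * max(field) & fg > 0

  # internal structures: greedy placement with minimum separation so each
  # label survives; retry with a fresh substream if placement fails
  smask <- matrix(0, h, w)
  n <- config$n_structures
  if (n > 0) {
    X <- matrix(seq_len(w), h, w, byrow = TRUE)
    Y <- matrix(seq_len(h), h, w)
    place_structures <- function() {
      cand <- which(interior)
      if (length(cand) < n) return(NULL)
      centers <- matrix(NA_real_, n, 2)
      radii <- runif(n, 0.035, 0.065) * mind
      stretch <- matrix(runif(2 * n, 0.7, 1.3), n, 2)
      sel <- integer(0)
      for (i in seq_len(n)) {
        found <- FALSE
        for (try in 1:300) {
          p <- sample(cand, 1L)
          py <- (p - 1L) %% h + 1L
          px <- (p - 1L) %/% h + 1L
          if (i == 1L || all(sqrt((centers[sel, 1] - px)^2 +
                                  (centers[sel, 2] - py)^2) >
                             2.4 * max(radii))) {
            centers[i, ] <- c(px, py)
            sel <- c(sel, i)
            found <- TRUE
            break
          }
        }
        if (!found) return(NULL)
      }
      list(centers = centers, radii = radii, stretch = stretch)
    }
    ok <- FALSE
    for (attempt in 0:19) {
      smask[] <- 0
      placed <- with_substream(seed, "structures", attempt,
                               place_structures())
      if (is.null(placed)) next
      for (i in seq_len(n)) {
        rx <- placed$radii[i] * placed$stretch[i, 1]
        ry <- placed$radii[i] * placed$stretch[i, 2]
        ell <- ((X - placed$centers[i, 1]) / rx)^2 +
               ((Y - placed$centers[i, 2]) / ry)^2 < 1
        smask[ell & fg > 0] <- i
      }
      if (all(seq_len(n) %in% unique(smask[smask > 0]))) { ok <- TRUE; break }
    }
    if (!ok) stop2("could not place %d structures inside the foreground; %s",
                   n, "reduce n_structures or enlarge the image")
  }

  hist_img <- .render_modality(fg, smask, .palette_histology)
  snap_img <- .render_modality(fg, smask, .palette_snapshot)

  # fine-grain texture on the histology-like rendering
  hist_img <- with_substream(seed, "texture-hist", 0L, {
    fine <- matrix(runif(h * w, -0.035, 0.035), h, w)
    base <- matrix(runif(h * w, -0.008, 0.008), h, w)
    for (c in 1:3)
      hist_img[, , c] <- hist_img[, , c] + base + fine * (fg > 0)
    hist_img
  })
  # coarse multiplicative shading on the snapshot-like rendering
  snap_img <- with_substream(seed, "texture-snap", 0L, {
    coarse <- resize_image(matrix(runif(48, 0.85, 1.15), 6, 8), h, w,
                           mode = "bilinear")
    base <- matrix(runif(h * w, -0.006, 0.006), h, w)
    for (c in 1:3)
      snap_img[, , c] <- snap_img[, , c] * ifelse(fg > 0, coarse, 1) + base
    snap_img
  })

  # tear / hole artifact on the histology-like rendering only
  hist_img <- with_substream(seed, "artifact", 0L, {
    if (runif(1) < config$artifact_rate && sum(fg) > 0) {
      type <- sample(c("tear", "hole"), 1L)
      if (type == "hole") {
        cand <- which(interior)
        p <- sample(cand, 1L)
        py <- (p - 1L) %% h + 1L; px <- (p - 1L) %/% h + 1L
        r <- runif(1, 0.04, 0.08) * mind
        X <- matrix(seq_len(w), h, w, byrow = TRUE)
        Y <- matrix(seq_len(h), h, w)
        hole <- ((X - px)^2 + (Y - py)^2) < r^2
        hist_img <- .paint_mask(hist_img, hole & fg > 0,
                                .palette_histology$background)
      } else {
        # thin crack: walk from a boundary point toward the centroid,
        # eroding a narrow polyline
        idx <- which(fg > 0)
        ys <- (idx - 1L) %% h + 1L; xs <- (idx - 1L) %/% h + 1L
        cy0 <- mean(ys); cx0 <- mean(xs)
        b <- sample(length(idx), 1L)
        sy <- ys[b]; sx <- xs[b]
        len <- runif(1, 0.5, 0.8)
        steps <- 60L
        jit <- cumsum(rnorm(steps, 0, 0.8))
        dirx <- cx0 - sx; diry <- cy0 - sy
        nrm <- sqrt(dirx^2 + diry^2) + 1e-9
        perpx <- -diry / nrm; perpy <- dirx / nrm
        th <- max(1, round(0.010 * mind))
        crack <- matrix(FALSE, h, w)
        for (t in seq_len(steps)) {
          f <- len * t / steps
          pxx <- sx + f * dirx + jit[t] * perpx
          pyy <- sy + f * diry + jit[t] * perpy
          x0 <- max(1L, round(pxx) - th); x1 <- min(w, round(pxx) + th)
          y0 <- max(1L, round(pyy) - th); y1 <- min(h, round(pyy) + th)
          for (xx in x0:x1) for (yy in y0:y1)
            if ((xx - pxx)^2 + (yy - pyy)^2 <= th^2) crack[yy, xx] <- TRUE
        }
        hist_img <- .paint_mask(hist_img, crack & fg > 0,
                                .palette_histology$background)
      }
    }
    hist_img
  })

  structure(list(histology_like = pmin(pmax(hist_img, 0), 1),
                 snapshot_like = pmin(pmax(snap_img, 0), 1),
                 foreground_mask = fg,
                 structure_mask = smask,
                 config = config),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("Multi-modal phantom pair %d x %d px, %d structures, seed %d\n",
              nrow(x$foreground_mask), ncol(x$foreground_mask),
              max(x$structure_mask), x$config$seed))
  cat(sprintf("  foreground: %.1f%% of pixels\n",
              100 * mean(x$foreground_mask)))
  invisible(x)
}

#' Generate a reproducible phantom dataset
#'
#' `n_pairs` independent phantom pairs from seed-derived substreams: pair
#' `i` is a pure function of `(config$seed, i)`, so regenerating any index
#' gives bit-identical output regardless of the others.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param config A [phantom_config()]; its `seed` is the root seed.
#' @return A list of `phantom_pair` objects, each with an `$id` element.
#' @export
generate_phantom_dataset <- function(n_pairs, config = phantom_config()) {
  if (n_pairs < 1) stop2("n_pairs must be >= 1")
  lapply(seq_len(n_pairs), function(i) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, "pair", i)
    p <- generate_phantom_pair(cfg)
    p$id <- i
    p
  })
}

#' Write a phantom dataset to disk
#'
#' Writes per-pair PNGs (histology-like and snapshot-like renderings as
#' 8-bit RGB; foreground mask as single-channel \{0, 255\}; structure
#' labels scaled to 8-bit) plus a `manifest.csv` with one record per pair.
#'
#' @param pairs A list from [generate_phantom_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest as a data frame, invisibly.
#' @export
write_phantom_dataset <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    id <- p$id %||% i
    paths <- file.path(dir, sprintf(c("pair%03d_histology.png",
                                      "pair%03d_snapshot.png",
                                      "pair%03d_mask.png",
                                      "pair%03d_structures.png"), id))
    write_image(p$histology_like, paths[1])
    write_image(p$snapshot_like, paths[2])
    write_image(p$foreground_mask, paths[3])
    nmax <- max(1, max(p$structure_mask))
    write_image(p$structure_mask / nmax, paths[4])
    data.frame(id = id, histology = paths[1], snapshot = paths[2],
               mask = paths[3], structures = paths[4],
               seed = p$config$seed)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
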