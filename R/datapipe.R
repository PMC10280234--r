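# HR -> LR bicubic degradation, channel-mean normalization, aligned patch
# extraction, rotation augmentation and the fixed-grid tiler.

cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * (t^3 - 5 * t^2 + 8 * t - 4), 0))
}

# n_out x n_in row-stochastic resampling matrix for one axis.
# Catmull-Rom style cubic (a = -0.5); on downscale the kernel is widened by
# 1/scale (antialias prefilter, the convention of high-quality resizers).
resize_matrix <- function(n_in, n_out, antialias = TRUE) {
  scale <- n_out / n_in
  s <- if (antialias && scale < 1) scale else 1
  support <- 2 / s
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / scale + 0.5  # center-aligned source coordinate (1-based)
    lo <- floor(src - support); hi <- ceiling(src + support)
    js <- lo:hi
    wts <- cubic_kernel((js - src) * s)
    keep <- wts != 0
    js <- js[keep]; wts <- wts[keep]
    js_cl <- pmin(pmax(js, 1L), n_in)  # replicate edges
    for (m in seq_along(js)) A[i, js_cl[m]] <- A[i, js_cl[m]] + wts[m]
    A[i, ] <- A[i, ] / sum(A[i, ])
  }
  A
}

#' Bicubic resize
#'
#' Separable bicubic interpolation with the a = -0.5 kernel; on downscale
#' the kernel support is widened by the inverse scale (antialias
#' prefilter). The exact resampling dialect is pinned here because PSNR
#' comparisons between super-resolution methods are sensitive to it.
#'
#' @param img RGB array in `[0,1]`, dim c(H, W, 3)
#' @param factor positive rational scale factor; `factor * dim` must be
#'   integer on both axes
#' @param antialias widen the kernel on downscale (default TRUE)
#' @param clip clamp the result to `[0,1]` (default TRUE)
#' @return resized RGB array
#' @export
bicubic_resize <- function(img, factor, antialias = TRUE, clip = TRUE) {
  assert_image(img)
  if (factor <= 0) stop_validation("factor must be positive")
  d <- dim(img)
  h_out <- d[1] * factor; w_out <- d[2] * factor
  if (abs(h_out - round(h_out)) > 1e-8 || abs(w_out - round(w_out)) > 1e-8)
    stop_validation("factor %g does not yield integer output dimensions", factor)
  h_out <- as.integer(round(h_out)); w_out <- as.integer(round(w_out))
  A <- resize_matrix(d[1], h_out, antialias)
  B <- resize_matrix(d[2], w_out, antialias)
  out <- array(0, dim = c(h_out, w_out, 3L))
  for (c in 1:3) out[, , c] <- A %*% img[, , c] %*% t(B)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Per-channel normalization statistics
#'
#' Dataset-wide RGB channel means subtracted from every input before the
#' network and added back to its output, so the network predicts residuals
#' around the dataset mean. Defaults are the stained-tissue training-set
#' means (0.7204, 0.4298, 0.6397).
#' @param mean_r,mean_g,mean_b channel means in `[0,1]`
#' @export
norm_stats <- function(mean_r = 0.7204, mean_g = 0.4298, mean_b = 0.6397) {
  m <- c(mean_r, mean_g, mean_b)
  if (any(m < 0) || any(m > 1)) stop_validation("channel means must lie in [0,1]")
  structure(list(mean_r = mean_r, mean_g = mean_g, mean_b = mean_b),
            class = "norm_stats")
}

stats_vec <- function(stats) c(stats$mean_r, stats$mean_g, stats$mean_b)

#' Compute normalization statistics from images
#'
#' Per-channel pixel means over all listed images (pixel-weighted, so
#' images of different sizes contribute by area).
#' @param images list of RGB arrays, or a character vector of PNG paths
#' @return a [norm_stats()]
#' @export
compute_norm_stats <- function(images) {
  if (is.character(images)) images <- lapply(images, read_image_patch)
  if (length(images) == 0) stop_validation("empty image list")
  sums <- c(0, 0, 0); npix <- 0
  for (img in images) {
    assert_image(img)
    sums <- sums + apply(img, 3L, sum)
    npix <- npix + prod(dim(img)[1:2])
  }
  m <- sums / npix
  norm_stats(m[1], m[2], m[3])
}

#' Subtract channel means
#' @param img RGB array
#' @param stats a [norm_stats()]
#' @export
apply_normalization <- function(img, stats) {
  assert_image(img)
  sweep(img, 3L, stats_vec(stats), `-`)
}

#' Add channel means back (inverse of [apply_normalization()])
#' @param img normalized array
#' @param stats a [norm_stats()]
#' @param check internal; skip range validation for raw network outputs
#' @export
invert_normalization <- function(img, stats, check = TRUE) {
  sweep(img, 3L, stats_vec(stats), `+`)
}

#' Build an aligned HR/LR pair by bicubic degradation
#'
#' The whole HR image is degraded once; training crops are later taken from
#' the pre-degraded LR with aligned HR windows, avoiding per-crop
#' resampling bias.
#' @param hr HR image, dimensions divisible by `scale`
#' @param scale integer degradation factor
#' @return object of class `patch_pair` with elements `lr`, `hr`, `scale`
#' @export
make_pair <- function(hr, scale) {
  assert_image(hr, "hr")
  d <- dim(hr)
  if (d[1] %% scale != 0L || d[2] %% scale != 0L)
    stop_validation("HR dimensions %dx%d not divisible by scale %d",
                    d[1], d[2], scale)
  structure(list(lr = bicubic_resize(hr, 1 / scale), hr = hr,
                 scale = as.integer(scale)), class = "patch_pair")
}

default_patch_size <- function(scale) if (scale == 3L) 48L else 64L

#' Extract an aligned random training crop from a pair
#'
#' LR crop of `patch_size` (default 64, or 48 at scale 3) with the exactly
#' aligned `scale`-times HR window.
#' @param pair a [make_pair()] result
#' @param seed optional integer seed for the crop position (caller RNG
#'   preserved); NULL draws from the current RNG
#' @param patch_size LR crop side length
#' @return a `patch_pair` of crops
#' @export
extract_training_patch <- function(pair, seed = NULL,
                                   patch_size = default_patch_size(pair$scale)) {
  d <- dim(pair$lr)
  if (d[1] < patch_size || d[2] < patch_size)
    stop_validation("LR image %dx%d smaller than patch size %d",
                    d[1], d[2], patch_size)
  draw <- function() c(sample.int(d[1] - patch_size + 1L, 1L),
                       sample.int(d[2] - patch_size + 1L, 1L))
  ij <- if (is.null(seed)) draw() else with_seed(seed, draw())
  i <- ij[1]; j <- ij[2]; s <- pair$scale
  lr <- pair$lr[i:(i + patch_size - 1L), j:(j + patch_size - 1L), , drop = FALSE]
  hr <- pair$hr[((i - 1L) * s + 1L):((i + patch_size - 1L) * s),
                ((j - 1L) * s + 1L):((j + patch_size - 1L) * s), , drop = FALSE]
  structure(list(lr = lr, hr = hr, scale = s), class = "patch_pair")
}

#' Rotate an image by k * 90 degrees counter-clockwise
#'
#' Coordinate mapping for one turn: `out[x, H - 1 - y] = in[y, x]`
#' (0-based).
#' @param img RGB array
#' @param k number of quarter turns (0-3)
#' @export
rot90_image <- function(img, k = 1L) {
  k <- as.integer(k) %% 4L
  for (turn in seq_len(k)) {
    d <- dim(img)
    out <- array(0, dim = c(d[2], d[1], d[3]))
    for (c in seq_len(d[3])) out[, , c] <- t(img[, , c])[, d[1]:1]
    img <- out
  }
  img
}

#' Random 90-degree rotation augmentation
#'
#' Rotates LR and HR by the same multiple of 90 degrees, k drawn uniformly
#' from {0, 1, 2, 3} (rotation only; no flips).
#' @param pair a `patch_pair`
#' @param k fixed number of quarter turns, or NULL to draw randomly
#' @param seed optional seed for the draw (caller RNG preserved)
#' @export
augment_rot90 <- function(pair, k = NULL, seed = NULL) {
  if (is.null(k)) {
    draw <- function() sample.int(4L, 1L) - 1L
    k <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  structure(list(lr = rot90_image(pair$lr, k), hr = rot90_image(pair$hr, k),
                 scale = pair$scale), class = "patch_pair")
}

#' Split an image into a non-overlapping grid of square tiles
#'
#' Row-major order; `(H/tile) * (W/tile)` tiles (e.g. 64 tiles of 128 from
#' a 1024 x 1024 patch).
#' @param img RGB array with dimensions divisible by `tile`
#' @param tile tile side length
#' @return list of RGB arrays
#' @export
tile_image <- function(img, tile) {
  assert_image(img)
  d <- dim(img)
  if (d[1] %% tile != 0L || d[2] %% tile != 0L)
    stop_validation("dimensions %dx%d not divisible by tile %d", d[1], d[2], tile)
  nr <- d[1] %/% tile; nc <- d[2] %/% tile
  out <- vector("list", nr * nc)
  idx <- 1L
  for (i in seq_len(nr)) {        # row-major: rows outer, columns inner
    for (j in seq_len(nc)) {
      out[[idx]] <- img[((i - 1L) * tile + 1L):(i * tile),
                        ((j - 1L) * tile + 1L):(j * tile), , drop = FALSE]
      idx <- idx + 1L
    }
  }
  out
}

#' Read an 8-bit RGB PNG as a unit-scale array
#' @param path PNG file
#' @export
read_image_patch <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a unit-scale RGB array as an 8-bit PNG
#'
#' Values are quantized to 8 bits with round-half-away-from-zero before
#' writing.
#' @param img RGB array in `[0,1]`
#' @param path output file
#' @export
write_image_patch <- function(img, path) {
  assert_image(img)
  png::writePNG(quantize8(img), path)
  invisible(path)
}
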