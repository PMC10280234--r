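# Seeded generator of histology-like RGB patches: multi-octave value noise
# mapped onto an eosin-pink / hematoxylin-purple palette, dark elliptical
# nuclei, and an optional contiguous white (background) region of
# controlled area. Statistical stand-ins for stained-tissue patches, not
# diagnostically realistic images.

#' Fixture generator specification
#'
#' @param size patch side length in pixels (>= 64)
#' @param n_images number of patches for [generate_dataset()]
#' @param seed master seed; each patch is a pure function of (seed, index)
#' @param target_mean length-3 target RGB dataset mean of pure-tissue
#'   patches (default c(0.72, 0.43, 0.64), the stained-tissue palette)
#' @param white_fraction fraction of pixels in `[0, 1)` belonging to a
#'   contiguous white background region (gray >= 225)
#' @param nucleus_density expected nuclei per 64 x 64 tissue tile
#' @param texture_scale relative spatial frequency of the tissue texture
#' @export
fixture_spec <- function(size = 256L, n_images = 16L, seed = 1L,
                         target_mean = c(0.72, 0.43, 0.64),
                         white_fraction = 0, nucleus_density = 10,
                         texture_scale = 1) {
  size <- as.integer(size)
  if (size < 64L) stop_validation("size must be at least 64")
  if (white_fraction < 0 || white_fraction >= 1)
    stop_validation("white_fraction must lie in [0, 1)")
  structure(list(size = size, n_images = as.integer(n_images),
                 seed = as.integer(seed), target_mean = target_mean,
                 white_fraction = white_fraction,
                 nucleus_density = nucleus_density,
                 texture_scale = texture_scale),
            class = "fixture_spec")
}

# smooth random field: coarse uniform grid upsampled bicubically to n x n
noise_field <- function(n, grid) {
  grid <- max(4L, as.integer(grid))
  m <- matrix(runif(grid * grid), grid, grid)
  A <- resize_matrix(grid, n, antialias = FALSE)
  A %*% m %*% t(A)
}

#' Generate one deterministic histology-like patch
#'
#' Deterministic per (spec$seed, index): the caller's RNG state is left
#' untouched. Tissue pixels blend two stain colors placed symmetrically
#' around `target_mean` along a rank-uniformized multi-octave noise field
#' (so the expected tissue mean equals the target), with dark elliptical
#' nuclei and fine speckle providing genuine high-frequency content. When
#' `white_fraction > 0`, a contiguous wavy-edged band of exactly that many
#' pixels (to rounding) is set to near-white (gray >= 225).
#'
#' @param spec a [fixture_spec()]
#' @param index patch index (1-based)
#' @return RGB array, dim c(size, size, 3)
#' @export
generate_patch <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$size
  with_seed(derive_seed(spec$seed, index), {
    f <- spec$texture_scale
    t_field <- 0.35 * noise_field(n, n * f / 32) +
      0.30 * noise_field(n, n * f / 16) +
      0.20 * noise_field(n, n * f / 8) +
      0.15 * noise_field(n, n * f / 4)
    t_field <- matrix(rank(t_field, ties.method = "first") / (n * n), n, n)
    delta <- c(0.19, 0.23, 0.16)
    c_light <- pmin(1, spec$target_mean + delta)   # eosin-like pink
    c_dark <- pmax(0, spec$target_mean - delta)    # hematoxylin-like purple
    img <- array(0, dim = c(n, n, 3L))
    for (c in 1:3)
      img[, , c] <- c_dark[c] + (c_light[c] - c_dark[c]) * t_field
    # elliptical nuclei
    n_nuc <- round(spec$nucleus_density * (n / 64)^2)
    if (n_nuc > 0) {
      nucleus_col <- pmax(0, spec$target_mean - c(0.34, 0.28, 0.20))
      xi <- matrix(rep(seq_len(n), n), n, n)
      yj <- t(xi)
      for (q in seq_len(n_nuc)) {
        cx <- runif(1, 1, n); cy <- runif(1, 1, n)
        a <- runif(1, 2, 4.5) * n / 128; b <- runif(1, 2, 4.5) * n / 128
        th <- runif(1, 0, pi)
        dx <- xi - cx; dy <- yj - cy
        u <- (dx * cos(th) + dy * sin(th)) / a
        v <- (-dx * sin(th) + dy * cos(th)) / b
        inside <- (u * u + v * v) <= 1
        if (!any(inside)) next
        for (c in 1:3) {
          ch <- img[, , c]
          ch[inside] <- 0.25 * ch[inside] + 0.75 * nucleus_col[c]
          img[, , c] <- ch
        }
      }
    }
    # fine speckle for high-frequency energy
    img <- img + array(runif(3 * n * n, -0.015, 0.015), dim = dim(img))
    img <- pmin(pmax(img, 0), 1)
    if (spec$white_fraction > 0) {
      n_white <- round(spec$white_fraction * n * n)
      edge <- noise_field(n, 6)[, 1]
      score <- t(matrix(rep(seq_len(n), n), n, n)) +
        0.15 * n * matrix(rep(edge, n), n, n)  # wavy left-to-right band
      thr <- sort(score)[n_white]
      white <- score <= thr
      wnoise <- runif(n * n, 0, 0.02)
      for (c in 1:3) {
        ch <- img[, , c]
        ch[white] <- 0.97 + wnoise[white]
        img[, , c] <- pmin(ch, 1)
      }
    }
    img
  })
}

#' Generate a fixture dataset on disk
#'
#' Writes `n_images` PNGs (`fixture_0001.png`, ...) plus `truth.tsv`
#' recording, for each patch, the white fraction and channel means measured
#' on the quantized 8-bit image actually written.
#'
#' @param spec a [fixture_spec()]
#' @param out_dir output directory (created if missing)
#' @return the truth table data.frame, invisibly
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(spec$n_images), function(i) {
    img <- quantize8(generate_patch(spec, i))
    path <- file.path(out_dir, sprintf("fixture_%04d.png", i))
    write_image_patch(img, path)
    m <- apply(img, 3L, mean)
    data.frame(index = i, path = path, white_fraction = white_fraction(img),
               mean_r = m[1], mean_g = m[2], mean_b = m[3],
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(truth)
}
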