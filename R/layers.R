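# Primitive network layers: same-padded convolution (C++ backend) and the
# sub-pixel shuffle. Feature maps are plain arrays with dim c(H, W, C).

conv2d <- function(x, w, b) {
  conv2d_fwd_cpp(x, w, b)
}

conv2d_grad <- function(x, w, dy) {
  conv2d_bwd_cpp(x, w, dy)
}

conv_init <- function(k, c_in, c_out, gain = 2) {
  # Kaiming fan-in normal initialization; biases zero
  sd <- sqrt(gain / (k * k * c_in))
  w <- array(rnorm(k * k * c_in * c_out, sd = sd), dim = c(k, k, c_in, c_out))
  list(w = w, b = numeric(c_out))
}

#' Sub-pixel shuffle (depth-to-space)
#'
#' Rearranges an \eqn{H \times W \times r^2C} feature map into an
#' \eqn{rH \times rW \times C} map. Output pixel \eqn{(ri+dy, rj+dx)} of
#' channel \eqn{c} is input pixel \eqn{(i, j)} of channel
#' \eqn{c\,r^2 + dy\,r + dx} (0-based), the standard sub-pixel convolution
#' ordering.
#'
#' @param x array with dim c(H, W, r^2 * C)
#' @param r integer upscaling factor per shuffle
#' @return array with dim c(r*H, r*W, C)
#' @export
pixel_shuffle <- function(x, r) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop_validation("pixel_shuffle expects an H x W x C array")
  if (d[3] %% (r * r) != 0L)
    stop_validation("channel count %d not divisible by r^2 = %d", d[3], r * r)
  H <- d[1]; W <- d[2]; C <- d[3] %/% (r * r)
  out <- array(0, dim = c(r * H, r * W, C))
  for (c in seq_len(C)) {
    for (dy in 0:(r - 1)) {
      for (dx in 0:(r - 1)) {
        cin <- (c - 1) * r * r + dy * r + dx + 1
        out[seq.int(dy + 1, r * H, by = r), seq.int(dx + 1, r * W, by = r), c] <-
          x[, , cin]
      }
    }
  }
  out
}

# exact inverse permutation (space-to-depth); the backward pass of pixel_shuffle
pixel_unshuffle <- function(y, r) {
  d <- dim(y)
  if (d[1] %% r != 0L || d[2] %% r != 0L)
    stop_validation("dimensions not divisible by r")
  H <- d[1] %/% r; W <- d[2] %/% r; C <- d[3]
  out <- array(0, dim = c(H, W, C * r * r))
  for (c in seq_len(C)) {
    for (dy in 0:(r - 1)) {
      for (dx in 0:(r - 1)) {
        cin <- (c - 1) * r * r + dy * r + dx + 1
        out[, , cin] <-
          y[seq.int(dy + 1, d[1], by = r), seq.int(dx + 1, d[2], by = r), c]
      }
    }
  }
  out
}

# Gaussian window as a (k, k, 1, 1) kernel for conv2d, normalized to sum 1
gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- outer(g1, g1)
  array(g / sum(g), dim = c(size, size, 1, 1))
}

# same-padded single-channel filtering of an H x W matrix
filter2d <- function(m, kern) {
  x <- array(m, dim = c(dim(m), 1L))
  conv2d(x, kern, 0)[, , 1]
}
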