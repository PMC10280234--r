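# Training objective (L1 + MSE + SSIM combination) and evaluation metrics
# (PSNR, SSIM). The SSIM gradient is derived analytically with respect to
# the Gaussian-filtered local statistics, which is what makes the combined
# loss trainable without an autodiff framework.

#' Combined-loss weights
#'
#' Non-negative weights (alpha, beta, gamma) of the L1, MSE and SSIM terms.
#' Defaults (0.8, 0.1, 0.1), the grid-searched optimum for stained-tissue
#' super-resolution.
#' @param alpha,beta,gamma non-negative reals, not all zero
#' @export
loss_weights <- function(alpha = 0.8, beta = 0.1, gamma = 0.1) {
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop_validation("loss weights must be non-negative")
  if (alpha + beta + gamma <= 0)
    stop_validation("at least one loss weight must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' SSIM parameters
#'
#' The reference parameterization: 11x11 Gaussian window with sigma 1.5,
#' stabilizers k1 = 0.01 and k2 = 0.03, dynamic range 1.0 for images on the
#' unit scale. Local statistics use same-padded filtering and the
#' (window-1)/2 border is cropped before averaging the index map.
#' @param window_size odd window width >= 3
#' @param gaussian_sigma Gaussian window standard deviation in pixels
#' @param k1,k2 positive stabilizer constants
#' @param dynamic_range value range of the inputs (1.0 on the unit scale)
#' @export
ssim_params <- function(window_size = 11L, gaussian_sigma = 1.5,
                        k1 = 0.01, k2 = 0.03, dynamic_range = 1.0) {
  window_size <- as.integer(window_size)
  if (window_size < 3L || window_size %% 2L != 1L)
    stop_validation("window_size must be an odd integer >= 3")
  if (k1 <= 0 || k2 <= 0) stop_validation("k1 and k2 must be positive")
  structure(list(window_size = window_size, gaussian_sigma = gaussian_sigma,
                 k1 = k1, k2 = k2, dynamic_range = dynamic_range),
            class = "ssim_params")
}

#' Mean squared error
#'
#' Mean of squared per-pixel differences over all pixels and channels.
#' @param pred,target arrays of identical shape
#' @export
mse_loss <- function(pred, target) {
  assert_same_shape(pred, target)
  mean((pred - target)^2)
}

#' Mean absolute (L1) error
#' @param pred,target arrays of identical shape
#' @export
l1_loss <- function(pred, target) {
  assert_same_shape(pred, target)
  mean(abs(pred - target))
}

# n x n banded Toeplitz matrix applying a zero-padded 1-D Gaussian; the
# 2-D window is separable, so filtering is Fh %*% m %*% Fw (two GEMMs),
# and symmetry of the band makes the operator self-adjoint.
gauss_band <- function(n, win, sigma) {
  half <- (win - 1L) %/% 2L
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  M <- matrix(0, n, n)
  for (o in -half:half) {
    i <- max(1L, 1L - o):min(n, n - o)
    M[cbind(i, i + o)] <- g1[o + half + 1L]
  }
  M
}

# per-channel filtered SSIM statistics; x, y are H x W matrices
ssim_stats_channel <- function(x, y, Fh, Fw, C1, C2) {
  filt <- function(m) Fh %*% m %*% Fw
  ux <- filt(x); uy <- filt(y)
  uxx <- filt(x * x); uyy <- filt(y * y)
  uxy <- filt(x * y)
  sx <- uxx - ux * ux; sy <- uyy - uy * uy; sxy <- uxy - ux * uy
  A1 <- 2 * ux * uy + C1; A2 <- 2 * sxy + C2
  B1 <- ux * ux + uy * uy + C1; B2 <- sx + sy + C2
  list(ux = ux, uy = uy, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       S = (A1 * A2) / (B1 * B2))
}

ssim_prepare <- function(pred, target, params) {
  assert_same_shape(pred, target)
  d <- dim(pred)
  if (is.null(d)) { pred <- array(pred, c(length(pred), 1, 1)); d <- dim(pred) }
  if (length(d) == 2L) { dim(pred) <- c(d, 1L); dim(target) <- c(d, 1L); d <- dim(pred) }
  win <- params$window_size
  if (d[1] < win || d[2] < win)
    stop_validation("SSIM window (%d) larger than image (%dx%d)", win, d[1], d[2])
  list(pred = pred, target = target, d = d,
       Fh = gauss_band(d[1], win, params$gaussian_sigma),
       Fw = gauss_band(d[2], win, params$gaussian_sigma),
       pad = (win - 1L) %/% 2L,
       C1 = (params$k1 * params$dynamic_range)^2,
       C2 = (params$k2 * params$dynamic_range)^2)
}

#' Structural similarity index
#'
#' Mean local SSIM over all channels, computed with Gaussian-weighted local
#' statistics and border cropping (see [ssim_params()]). Identical images
#' score exactly 1. The raw index is reported without clipping, so strongly
#' anticorrelated content can score slightly below 0 even though similarity
#' is conventionally quoted on the [0, 1] scale.
#' @param pred,target arrays of identical shape (matrix or H x W x C)
#' @param params an [ssim_params()]
#' @export
ssim_index <- function(pred, target, params = ssim_params()) {
  pr <- ssim_prepare(pred, target, params)
  ii <- (pr$pad + 1L):(pr$d[1] - pr$pad)
  jj <- (pr$pad + 1L):(pr$d[2] - pr$pad)
  vals <- vapply(seq_len(pr$d[3]), function(c) {
    st <- ssim_stats_channel(pr$pred[, , c], pr$target[, , c], pr$Fh, pr$Fw,
                             pr$C1, pr$C2)
    mean(st$S[ii, jj])
  }, numeric(1))
  mean(vals)
}

#' SSIM loss
#'
#' `1 - ssim_index(pred, target)`; 0 for identical images, at most 2.
#' @inheritParams ssim_index
#' @export
ssim_loss <- function(pred, target, params = ssim_params()) {
  1 - ssim_index(pred, target, params)
}

# gradient of mean-SSIM with respect to pred; returns list(index, grad)
ssim_index_grad <- function(pred, target, params = ssim_params()) {
  pr <- ssim_prepare(pred, target, params)
  d <- pr$d
  mask <- matrix(0, d[1], d[2])
  ii <- (pr$pad + 1L):(d[1] - pr$pad)
  jj <- (pr$pad + 1L):(d[2] - pr$pad)
  mask[ii, jj] <- 1 / (length(ii) * length(jj) * d[3])
  grad <- array(0, d)
  total <- 0
  filt <- function(m) pr$Fh %*% m %*% pr$Fw
  for (c in seq_len(d[3])) {
    x <- pr$pred[, , c]; y <- pr$target[, , c]
    st <- ssim_stats_channel(x, y, pr$Fh, pr$Fw, pr$C1, pr$C2)
    total <- total + sum(st$S * mask)
    BB <- st$B1 * st$B2
    dS_dux <- 2 * st$uy * (st$A2 - st$A1) / BB -
      st$S * (2 * st$ux / st$B1 - 2 * st$ux / st$B2)
    dS_duxx <- -st$S / st$B2
    dS_duxy <- 2 * st$A1 / BB
    # the symmetric band matrices make the filtering self-adjoint
    grad[, , c] <- filt(mask * dS_dux) + 2 * x * filt(mask * dS_duxx) +
      y * filt(mask * dS_duxy)
  }
  list(index = total, grad = grad)
}

#' Combined super-resolution training loss
#'
#' `alpha * L1 + beta * MSE + gamma * (1 - SSIM)`, evaluated in image space.
#' @param pred,target arrays of identical shape
#' @param weights a [loss_weights()]
#' @param params an [ssim_params()] (used only when gamma > 0)
#' @export
combined_loss <- function(pred, target, weights = loss_weights(),
                          params = ssim_params()) {
  stopifnot(inherits(weights, "loss_weights"))
  out <- weights$alpha * l1_loss(pred, target) +
    weights$beta * mse_loss(pred, target)
  if (weights$gamma > 0)
    out <- out + weights$gamma * ssim_loss(pred, target, params)
  out
}

# loss value, its components, and the gradient with respect to pred
combined_loss_grad <- function(pred, target, weights = loss_weights(),
                               params = ssim_params()) {
  n <- length(pred)
  diff <- pred - target
  l1 <- mean(abs(diff)); mse <- mean(diff^2)
  grad <- (weights$alpha * sign(diff) + weights$beta * 2 * diff) / n
  sl <- 0
  if (weights$gamma > 0) {
    sg <- ssim_index_grad(pred, target, params)
    sl <- 1 - sg$index
    grad <- grad - weights$gamma * sg$grad
  }
  list(l1 = l1, mse = mse, ssim_loss = sl,
       total = weights$alpha * l1 + weights$beta * mse + weights$gamma * sl,
       grad = grad)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(peak^2 / MSE)`; identical images return `Inf`.
#' @param pred,target arrays of identical shape
#' @param peak signal peak (1.0 on the unit scale)
#' @export
psnr <- function(pred, target, peak = 1.0) {
  m <- mse_loss(pred, target)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Write a per-image metrics report
#'
#' @param report data.frame with columns file, scale, psnr_db, ssim
#' @param path output CSV path
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(all(c("file", "scale", "psnr_db", "ssim") %in% names(report)))
  write.table(report[, c("file", "scale", "psnr_db", "ssim")], path,
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
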