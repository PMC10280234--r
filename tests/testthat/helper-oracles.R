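# Independent brute-force reference implementations used as oracles.
# Deliberately naive (scalar loops, direct formulas) and sharing no code
# with the package's computational paths.

rand_image <- function(h, w, seed = 1) {
  with_test_seed(seed, array(runif(h * w * 3), dim = c(h, w, 3L)))
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# zero-padded same cross-correlation, scalar loops
naive_conv <- function(x, w, b) {
  k <- dim(w)[1]; pad <- (k - 1) / 2
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(w)[4]
  out <- array(0, c(H, W, Cout))
  for (o in 1:Cout) for (i in 1:H) for (j in 1:W) {
    acc <- b[o]
    for (c in 1:Cin) for (di in 1:k) for (dj in 1:k) {
      ii <- i + di - 1 - pad; jj <- j + dj - 1 - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * w[di, dj, c, o]
    }
    out[i, j, o] <- acc
  }
  out
}

# direct index-mapping enumeration of the sub-pixel rearrangement
naive_pixel_shuffle <- function(x, r) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3] / (r * r)
  out <- array(NA_real_, c(r * H, r * W, C))
  for (c in 0:(C - 1)) for (y in 0:(r * H - 1)) for (xx in 0:(r * W - 1)) {
    cin <- c * r * r + (y %% r) * r + (xx %% r)
    out[y + 1, xx + 1, c + 1] <- x[y %/% r + 1, xx %/% r + 1, cin + 1]
  }
  out
}

# windowed Gaussian SSIM by explicit window extraction; all retained
# windows lie fully inside the image, so padding never enters
naive_ssim <- function(x, y, win = 11, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                       L = 1) {
  if (length(dim(x)) == 3)
    return(mean(vapply(seq_len(dim(x)[3]), function(c)
      naive_ssim(x[, , c], y[, , c], win, sigma, k1, k2, L), numeric(1))))
  half <- (win - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  G <- outer(g1, g1); G <- G / sum(G)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  H <- nrow(x); W <- ncol(x)
  vals <- numeric(0)
  for (i in (half + 1):(H - half)) for (j in (half + 1):(W - half)) {
    wx <- x[(i - half):(i + half), (j - half):(j + half)]
    wy <- y[(i - half):(i + half), (j - half):(j + half)]
    mx <- sum(G * wx); my <- sum(G * wy)
    sx <- sum(G * wx^2) - mx^2; sy <- sum(G * wy^2) - my^2
    sxy <- sum(G * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                ((mx^2 + my^2 + C1) * (sx + sy + C2)))
  }
  mean(vals)
}

# element-by-element accumulation of the pixel losses
naive_l1 <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

naive_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

# zero every convolution in the network body (CARB trunks + body tail)
zero_body <- function(model) {
  for (m in seq_along(model$params$carb)) {
    for (i in seq_along(model$params$carb[[m]]$conv)) {
      model$params$carb[[m]]$conv[[i]]$w[] <- 0
      model$params$carb[[m]]$conv[[i]]$b[] <- 0
    }
  }
  model$params$tail$w[] <- 0
  model$params$tail$b[] <- 0
  model
}

# synthetic ranking records (no image files behind them)
synth_records <- function(n, seed = 1) {
  with_test_seed(seed, data.frame(
    path = sprintf("img_%04d.png", seq_len(n)),
    white_fraction = runif(n, 0, 0.5),
    mean_r = runif(n, 0.4, 0.95), mean_g = runif(n, 0.1, 0.7),
    mean_b = runif(n, 0.3, 0.9), n_pixels = rep(64 * 64, n),
    stringsAsFactors = FALSE))
}
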