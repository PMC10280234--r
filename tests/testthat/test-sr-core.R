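test_that("channel gate lies strictly in (0,1) and zero weights give 1/2", {
  for (seed in 1:5) {
    f <- with_test_seed(seed, array(rnorm(8 * 6 * 16), c(8, 6, 16)))
    g <- with_test_seed(seed + 100, ca_retention(f, reduction = 4))
    expect_length(g, 16)
    expect_true(all(g > 0 & g < 1))
  }
  zw <- list(ds = list(w = matrix(0, 4, 16), b = numeric(4)),
             us = list(w = matrix(0, 16, 4), b = numeric(16)))
  f <- with_test_seed(1, array(rnorm(5 * 5 * 16), c(5, 5, 16)))
  expect_equal(ca_retention(f, weights = zw), rep(0.5, 16))
})

test_that("attention bottleneck width follows the sqrt(C) rule", {
  expect_identical(ca_descriptor_width(64, 8), 8L)
  expect_identical(ca_descriptor_width(16, round(sqrt(16))), 4L)
  expect_identical(ca_descriptor_width(3, 3), 1L)
  expect_identical(carn_config()$reduction, 8L)  # default C = 64
  expect_error(ca_descriptor_width(64, 0), "reduction")
  expect_error(ca_retention(array(Inf, c(4, 4, 2)), 1), "finite")
})

test_that("a CARB with zeroed trunk is the exact identity map", {
  cfg <- carn_config(scale = 2, n_carb = 1, channels = 8, reduction = 3)
  model <- carn_model(cfg, seed = 7)
  blk <- model$params$carb[[1]]
  for (i in seq_along(blk$conv)) {
    blk$conv[[i]]$w[] <- 0
    blk$conv[[i]]$b[] <- 0
  }
  f <- with_test_seed(2, array(rnorm(10 * 7 * 8), c(10, 7, 8)))
  expect_identical(carb_forward(f, blk), f)
})

test_that("carb_forward matches an independently coded composition", {
  cfg <- carn_config(scale = 2, n_carb = 1, channels = 8, reduction = 3)
  model <- carn_model(cfg, seed = 11)
  blk <- model$params$carb[[1]]
  f <- with_test_seed(3, array(rnorm(4 * 4 * 8), c(4, 4, 8)))
  # step-by-step oracle: conv, relu, conv, pool, down, relu, up, sigmoid,
  # per-channel scale, residual add -- all with naive loops
  t1 <- naive_conv(f, blk$conv[[1]]$w, blk$conv[[1]]$b)
  t1 <- pmax(t1, 0)
  t2 <- naive_conv(t1, blk$conv[[2]]$w, blk$conv[[2]]$b)
  pool <- vapply(1:8, function(c) mean(t2[, , c]), numeric(1))
  h <- pmax(drop(blk$ds$w %*% pool) + blk$ds$b, 0)
  g <- 1 / (1 + exp(-(drop(blk$us$w %*% h) + blk$us$b)))
  expected <- f
  for (c in 1:8) expected[, , c] <- f[, , c] + g[c] * t2[, , c]
  got <- carb_forward(f, blk)
  expect_lt(max(abs(got - expected)) / max(abs(expected)), 1e-6)
})

test_that("carb_forward preserves shape and rejects channel mismatch", {
  cfg <- carn_config(scale = 2, n_carb = 1, channels = 64)
  model <- carn_model(cfg, seed = 1)
  f <- with_test_seed(4, array(rnorm(16 * 16 * 64), c(16, 16, 64)))
  expect_identical(dim(carb_forward(f, model$params$carb[[1]])),
                   c(16L, 16L, 64L))
  bad <- array(0, c(16, 16, 32))
  expect_error(carb_forward(bad, model$params$carb[[1]]), "channel mismatch")
})

test_that("pixel shuffle matches the brute-force index mapping and inverts", {
  for (case in list(list(r = 2, h = 2, w = 2, c = 4),
                    list(r = 2, h = 3, w = 5, c = 8),
                    list(r = 3, h = 2, w = 4, c = 9))) {
    x <- with_test_seed(case$r + case$h,
                        array(rnorm(case$h * case$w * case$c),
                              c(case$h, case$w, case$c)))
    got <- pixel_shuffle(x, case$r)
    expect_lt(max(abs(got - naive_pixel_shuffle(x, case$r))), 1e-12)
    expect_identical(carnsr:::pixel_unshuffle(got, case$r), x)
  }
  expect_error(pixel_shuffle(array(0, c(2, 2, 3)), 2), "divisible")
})

test_that("upsampler layout: group counts and channel expansions", {
  expect_equal(upsampler_plan(2, 64)$n_groups, 1)
  expect_equal(upsampler_plan(4, 64)$n_groups, 2)
  expect_equal(upsampler_plan(8, 64)$n_groups, 3)
  expect_equal(upsampler_plan(3, 64)$n_groups, 1)
  expect_equal(upsampler_plan(3, 64)$groups[[1]]$expansion, 9)
  expect_equal(upsampler_plan(2, 64)$groups[[1]]$conv_out, 256)
  expect_error(upsampler_plan(5, 64), "unsupported scale")
})

test_that("forward output is exactly scale x input size for every scale", {
  for (s in c(2L, 3L, 4L, 8L)) {
    cfg <- carn_config(scale = s, n_carb = 1, channels = 8, reduction = 3)
    model <- carn_model(cfg, seed = 5)
    lr <- rand_image(9, 7, seed = s)
    out <- carn_forward(lr, model)
    expect_identical(dim(out), c(9L * s, 7L * s, 3L))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("zeroed body reduces the network to head + upsampler (long skip)", {
  cfg <- carn_config(scale = 2, n_carb = 3, channels = 8, reduction = 3)
  model <- zero_body(carn_model(cfg, seed = 9))
  lr <- rand_image(12, 12, seed = 21)
  x0 <- apply_normalization(lr, model$stats)
  p <- model$params
  # manual head -> upsample -> output composition, skipping the body
  f0 <- carnsr:::conv2d(x0, p$head$w, p$head$b)
  up <- pixel_shuffle(carnsr:::conv2d(f0, p$up[[1]]$w, p$up[[1]]$b), 2)
  manual <- carnsr:::conv2d(up, p$out$w, p$out$b)
  manual <- invert_normalization(manual, model$stats)
  got <- carn_forward(lr, model, clip = FALSE)
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("same seed gives bitwise-identical models and forward passes", {
  cfg <- carn_config(scale = 2, n_carb = 2, channels = 8, reduction = 3)
  m1 <- carn_model(cfg, seed = 42)
  m2 <- carn_model(cfg, seed = 42)
  expect_identical(m1$params, m2$params)
  lr <- rand_image(10, 10, seed = 3)
  expect_identical(carn_forward(lr, m1), carn_forward(lr, m2))
})

test_that("parameter and FLOP totals are affine in the number of blocks", {
  counts <- vapply(c(4L, 8L, 12L), function(n) {
    count_parameters(carn_model(carn_config(scale = 2, n_carb = n), seed = 1))
  }, numeric(1))
  expect_gt(counts[2], counts[1])
  expect_equal(counts[3] - counts[2], counts[2] - counts[1])
  flops <- vapply(c(4L, 8L, 12L), function(n) {
    count_flops(carn_model(carn_config(scale = 2, n_carb = n), seed = 1))
  }, numeric(1))
  expect_equal(flops[3] - flops[2], flops[2] - flops[1])
  expect_gt(flops[2], flops[1])
})

test_that("complexity report exposes its totals beside the reference budget", {
  model <- carn_model(carn_config(), seed = 1)
  rep <- expect_output(carn_complexity_report(model), "1.389 M")
  expect_identical(rep$parameters, count_parameters(model))
  expect_identical(rep$reference$parameters, 1.389e6)
  expect_identical(rep$reference$flops, 11.300e9)
})

test_that("configuration validation rejects invalid settings", {
  expect_error(carn_config(scale = 5), "unsupported scale")
  expect_error(carn_config(reduction = 0), "reduction")
  expect_error(carn_config(reduction = 65), "reduction")
  expect_error(carn_config(kernel_size = 4), "odd")
})
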