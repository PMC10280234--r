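# internal helpers shared across modules

stop_validation <- function(...) stop(sprintf(...), call. = FALSE)

assert_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_validation("%s must be an H x W x 3 array", arg)
  if (!all(is.finite(img)))
    stop_validation("%s contains non-finite values", arg)
  if (min(img) < 0 || max(img) > 1)
    stop_validation("%s must have values in [0, 1]", arg)
  invisible(img)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_validation("inputs must have identical dimensions (%s vs %s)",
                    paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(NULL)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Fold (seed, index) into one 31-bit stream id; keeps derived seeds valid R ints.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# 8-bit quantization used for PNG round-trips: round half away from zero.
quantize8 <- function(img) {
  v <- floor(abs(img) * 255 + 0.5) * sign(img)
  pmin(pmax(v, 0), 255) / 255
}
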